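# Reference CI-pattern fixture for the criteria engine: one row per
# measure x phenotype cell, reproducing the published summary pattern of a
# multi-centre psychosis/bipolar twin study (point estimates and 95% CIs as
# printed, to 2 dp). Columns: within-twin cross-trait correlation CI (the
# criterion-1 gate), cognitive h2 with CI, rg CI, rph_a CI, and the expected
# criteria outcome. Cells the study could not evaluate (no data) are absent.
criteria_fixture <- function() {
  row <- function(measure, phenotype, c1_lo, c1_hi, h2, h2_lo, h2_hi,
                  rg_lo, rg_hi, ra_lo, ra_hi, expect_endo, expect_stage) {
    data.frame(measure = measure, phenotype = phenotype,
               c1_lo = c1_lo, c1_hi = c1_hi,
               h2 = h2, h2_lo = h2_lo, h2_hi = h2_hi,
               rg_lo = rg_lo, rg_hi = rg_hi,
               ra_lo = ra_lo, ra_hi = ra_hi,
               expect_endo = expect_endo, expect_stage = expect_stage,
               stringsAsFactors = FALSE)
  }
  rbind(
    # --- schizophrenia (liability h2 fixed 0.84) ---
    row("iq",      "sz", -0.30, -0.16, 0.75, 0.52, 0.80, -0.28, -0.09,
        -0.23, -0.07, TRUE,  "pass"),
    row("swm_be",  "sz",  0.11,  0.28, 0.28, 0.02, 0.59,  0.14,  1.00,
         0.08,  0.28, TRUE,  "pass"),
    row("swm_st",  "sz", -0.05,  0.15, NA, NA, NA, NA, NA, NA, NA,
        FALSE, "gate"),
    row("prm_mcl", "sz", -0.04,  0.17, NA, NA, NA, NA, NA, NA, NA,
        FALSE, "gate"),
    row("prm_pc",  "sz", -0.30, -0.05, 0.42, 0.02, 0.66, -1.00, -0.09,
        -0.33, -0.05, TRUE,  "pass"),
    row("rvp",     "sz", -0.24, -0.01, 0.38, 0.02, 0.58, -1.00,  0.01,
        -0.24, -0.01, FALSE, "fail_c3"),
    row("ied_tt",  "sz", -0.06,  0.14, NA, NA, NA, NA, NA, NA, NA,
        FALSE, "gate"),
    row("ied_te",  "sz",  0.04,  0.24, 0.27, 0.01, 0.45,  0.06,  1.00,
         0.03,  0.26, TRUE,  "pass"),
    row("soc_mm",  "sz", -0.27, -0.07, 0.02, 0.00, 0.47, -1.00, -0.22,
        -0.25, -0.01, FALSE, "fail_c2"),
    row("soc_itt", "sz", -0.09,  0.12, NA, NA, NA, NA, NA, NA, NA,
        FALSE, "gate"),
    row("soc_stt", "sz",  0.02,  0.24, 0.52, 0.13, 0.73,  0.28,  0.64,
         0.06,  0.31, TRUE,  "pass"),
    # --- bipolar I disorder (liability h2 fixed 0.85) ---
    row("iq",      "bd1", -0.22, -0.06, 0.67, 0.45, 0.80, -0.34, -0.08,
        -0.24, -0.07, TRUE,  "pass"),
    row("swm_be",  "bd1",  0.09,  0.25, 0.29, 0.01, 0.59,  0.05,  1.00,
         0.03,  0.21, TRUE,  "pass"),
    row("swm_st",  "bd1",  0.03,  0.19, 0.08, 0.00, 0.44,  0.40,  1.00,
         0.01,  0.20, FALSE, "fail_c2"),
    row("prm_mcl", "bd1",  0.03,  0.21, 0.00, 0.00, 0.02, -1.00,  1.00,
        -0.06,  0.14, FALSE, "fail_c2"),
    row("prm_pc",  "bd1", -0.10,  0.08, NA, NA, NA, NA, NA, NA, NA,
        FALSE, "gate"),
    row("rvp",     "bd1", -0.25, -0.07, 0.44, 0.06, 0.58, -0.22,  0.05,
        -0.19,  0.03, FALSE, "fail_c3"),
    row("ied_tt",  "bd1",  0.03,  0.21, 0.26, 0.00, 0.38,  0.25,  1.00,
         0.01,  0.23, FALSE, "fail_c2"),
    # --- broad psychosis/bipolar phenotype (liability h2 fixed 0.90) ---
    row("iq",      "broad", -0.30, -0.17, 0.72, 0.49, 0.79, -0.37, -0.17,
        -0.28, -0.13, TRUE,  "pass"),
    row("swm_be",  "broad",  0.17,  0.31, 0.30, 0.03, 0.59,  0.22,  1.00,
         0.14,  0.29, TRUE,  "pass"),
    row("swm_st",  "broad",  0.06,  0.21, 0.09, 0.01, 0.44,  0.53,  1.00,
         0.07,  0.23, FALSE, "fail_c2"),
    row("prm_mcl", "broad",  0.06,  0.24, 0.01, 0.00, 0.04, -1.00,  1.00,
        -0.01,  0.19, FALSE, "fail_c2"),
    row("prm_pc",  "broad", -0.26, -0.08, 0.45, 0.02, 0.65, -1.00, -0.11,
        -0.29, -0.07, TRUE,  "pass"),
    row("rvp",     "broad", -0.27, -0.12, 0.42, 0.05, 0.57, -0.96, -0.13,
        -0.26, -0.08, TRUE,  "pass"),
    row("ied_tt",  "broad",  0.10,  0.25, 0.26, 0.01, 0.38,  0.14,  1.00,
         0.07,  0.24, TRUE,  "pass"),
    row("ied_te",  "broad",  0.12,  0.31, 0.27, 0.02, 0.44,  0.18,  1.00,
         0.09,  0.31, TRUE,  "pass"),
    row("soc_mm",  "broad", -0.33, -0.13, 0.04, 0.01, 0.50, -1.00, -0.22,
        -0.31, -0.08, FALSE, "fail_c2"),
    row("soc_itt", "broad", -0.02,  0.19, NA, NA, NA, NA, NA, NA, NA,
        FALSE, "gate"),
    row("soc_stt", "broad",  0.10,  0.32, 0.53, 0.14, 0.72,  0.17,  0.85,
         0.13,  0.37, TRUE,  "pass"))
}
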