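#' Pair-structured twin/sibling dataset
#'
#' A `twin_data` object wraps a data frame with one row per individual and
#' carries the names of the cognitive measures and diagnostic phenotypes it
#' contains. Required columns are `pair_id`, `member_index` (1 or 2) and
#' `zygosity` (`"MZ"`, `"DZ"` or `"SIB"`); diagnostic phenotypes are binary
#' `affected_<name>` columns; everything the schema does not claim as a
#' covariate (`age`, `sex`, `education`, `centre`) is treated as a cognitive
#' measure unless `measures` says otherwise. Missing values are `NA` (or empty
#' cells on disk); sentinel numerics are never interpreted as missing.
#'
#' @param data data frame, one row per individual.
#' @param measures character vector of cognitive measure column names. If
#'   `NULL`, all numeric columns not otherwise claimed are used.
#' @param phenotypes character vector of phenotype names (without the
#'   `affected_` prefix). If `NULL`, inferred from `affected_*` columns.
#' @return A `twin_data` object.
#' @export
twin_data <- function(data, measures = NULL, phenotypes = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  req <- c("pair_id", "member_index", "zygosity")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  data$zygosity <- toupper(as.character(data$zygosity))
  bad_z <- setdiff(unique(data$zygosity), c("MZ", "DZ", "SIB"))
  if (length(bad_z))
    stop("unknown zygosity code(s): ", paste(bad_z, collapse = ", "))
  if (!all(data$member_index %in% c(1L, 2L)))
    stop("member_index must be 1 or 2")
  key <- paste(data$pair_id, data$member_index)
  if (anyDuplicated(key))
    stop("duplicate (pair_id, member_index): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  # a pair must not mix zygosity codes
  zyg_per_pair <- tapply(data$zygosity, data$pair_id,
                         function(z) length(unique(z)))
  if (any(zyg_per_pair > 1))
    stop("pair(s) with inconsistent zygosity: ",
         paste(names(zyg_per_pair)[zyg_per_pair > 1], collapse = ", "))
  if (is.null(phenotypes)) {
    phenotypes <- sub("^affected_", "",
                      grep("^affected_", names(data), value = TRUE))
  }
  for (ph in phenotypes) {
    col <- paste0("affected_", ph)
    if (!col %in% names(data)) stop("missing phenotype column: ", col)
    v <- data[[col]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop("phenotype column ", col, " must be 0/1/NA")
  }
  covs <- intersect(c("age", "sex", "education", "centre"), names(data))
  if (is.null(measures)) {
    claimed <- c(req, covs, paste0("affected_", phenotypes))
    cand <- setdiff(names(data), claimed)
    measures <- cand[vapply(data[cand], is.numeric, logical(1))]
  } else {
    missing_m <- setdiff(measures, names(data))
    if (length(missing_m))
      stop("measure column(s) not in data: ", paste(missing_m, collapse = ", "))
  }
  structure(list(data = data, measures = measures, phenotypes = phenotypes),
            class = "twin_data")
}

#' @export
print.twin_data <- function(x, ...) {
  d <- x$data
  cat("<twin_data> ", nrow(d), " individuals in ",
      length(unique(d$pair_id)), " pairs\n", sep = "")
  cat("  zygosity: ",
      paste(names(table(d$zygosity)), table(d$zygosity),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  measures: ", paste(x$measures, collapse = ", "), "\n", sep = "")
  cat("  phenotypes: ", paste(x$phenotypes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
n_pairs <- function(x) UseMethod("n_pairs")

#' @export
n_pairs.twin_data <- function(x) length(unique(x$data$pair_id))

#' Read a pair-structured CSV
#'
#' One row per individual; columns `pair_id`, `member_index`, `zygosity`,
#' optional `affected_<phenotype>` binaries, cognitive measure columns, and
#' covariates `age`, `sex`, `education`, `centre`. Empty cells and `"NA"`
#' are the only missing-value codes.
#'
#' @param path CSV file path.
#' @inheritParams twin_data
#' @return A [twin_data] object.
#' @export
read_twin_csv <- function(path, measures = NULL, phenotypes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  twin_data(df, measures = measures, phenotypes = phenotypes)
}

#' Write a twin dataset back to CSV
#'
#' Round-trips through [read_twin_csv()]: reading the written file yields an
#' identical dataset.
#'
#' @param x a [twin_data] object.
#' @param path output CSV path.
#' @export
write_twin_csv <- function(x, path) {
  stopifnot(inherits(x, "twin_data"))
  utils::write.csv(x$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply cohort inclusion filters
#'
#' Removes individual members outside the age window or below the IQ floor.
#' The co-twin of an excluded member is retained, leaving an incomplete pair,
#' mirroring study practice of keeping incomplete pairs in the likelihood.
#'
#' @param x a [twin_data] object.
#' @param min_iq minimum IQ retained (members with `iq_measure` observed and
#'   below this are excluded). Default 70.
#' @param age_range inclusive age window in years. Default `c(16, 65)`.
#' @param iq_measure name of the IQ column used for the floor; ignored when
#'   absent.
#' @return A [twin_data] object with an `exclusion_log` attribute: a list with
#'   counts per reason and the excluded `(pair_id, member_index)` keys.
#'   Retrieve it with [exclusion_log()].
#' @export
apply_inclusion_filters <- function(x, min_iq = 70, age_range = c(16, 65),
                                    iq_measure = "iq") {
  stopifnot(inherits(x, "twin_data"))
  d <- x$data
  n0 <- nrow(d)
  drop_iq <- if (iq_measure %in% names(d))
    !is.na(d[[iq_measure]]) & d[[iq_measure]] < min_iq else rep(FALSE, n0)
  drop_age <- if ("age" %in% names(d))
    !is.na(d$age) & (d$age < age_range[1] | d$age > age_range[2])
  else rep(FALSE, n0)
  drop <- drop_iq | drop_age
  log <- list(
    n_before = n0,
    n_after = n0 - sum(drop),
    by_reason = c(iq = sum(drop_iq), age = sum(drop_age & !drop_iq)),
    total = sum(drop),
    excluded = data.frame(pair_id = d$pair_id[drop],
                          member_index = d$member_index[drop],
                          reason = ifelse(drop_iq[drop], "iq", "age"))
  )
  out <- twin_data(d[!drop, , drop = FALSE], x$measures, x$phenotypes)
  attr(out, "exclusion_log") <- log
  out
}

#' @rdname apply_inclusion_filters
#' @export
exclusion_log <- function(x) attr(x, "exclusion_log")

#' Covariate design matrix
#'
#' Builds the fixed-effect design used on the cognitive mean: centred age and
#' education, 0/1 sex, and research centre expanded to K-1 indicators against
#' a reference level. Centring constants are recorded so the same encoding can
#' be replayed on new data.
#'
#' @param x a [twin_data] object.
#' @param reference_centre reference level for the centre factor; default the
#'   first level encountered.
#' @param centres full set of centre labels (training-time levels). Unseen
#'   labels at encode time are an error.
#' @param centering named list of centring constants (`age`, `education`); if
#'   `NULL`, sample means of the available columns are used and recorded.
#' @return numeric matrix, one row per individual (same order as `x$data`),
#'   with attributes `centering`, `centres`, `reference_centre`.
#' @export
encode_covariates <- function(x, reference_centre = NULL, centres = NULL,
                              centering = NULL) {
  stopifnot(inherits(x, "twin_data"))
  d <- x$data
  cols <- list()
  ctr <- list()
  if ("age" %in% names(d)) {
    m <- if (!is.null(centering$age)) centering$age else
      mean(d$age, na.rm = TRUE)
    ctr$age <- m
    cols$age <- d$age - m
  }
  if ("sex" %in% names(d)) {
    sx <- d$sex
    if (!all(is.na(sx) | sx %in% c(0, 1))) stop("sex must be coded 0/1")
    cols$sex <- as.numeric(sx)
  }
  if ("education" %in% names(d)) {
    m <- if (!is.null(centering$education)) centering$education else
      mean(d$education, na.rm = TRUE)
    ctr$education <- m
    cols$education <- d$education - m
  }
  if ("centre" %in% names(d)) {
    lab <- as.character(d$centre)
    if (is.null(centres)) centres <- unique(lab[!is.na(lab)])
    unseen <- setdiff(unique(lab[!is.na(lab)]), centres)
    if (length(unseen))
      stop("unseen centre label(s): ", paste(unseen, collapse = ", "))
    if (is.null(reference_centre)) reference_centre <- centres[1]
    if (!reference_centre %in% centres)
      stop("reference_centre not among centre labels")
    others <- setdiff(centres, reference_centre)
    for (cc in others)
      cols[[paste0("centre_", cc)]] <- as.numeric(lab == cc)
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(d), ncol = 0)
  if (length(cols)) colnames(X) <- names(cols)
  attr(X, "centering") <- ctr
  attr(X, "centres") <- centres
  attr(X, "reference_centre") <- reference_centre
  X
}

# internal: one-row-per-pair layout used by the likelihood engines.
# Returns data.frame with y1,y2 (measure), d1,d2 (phenotype), zyg,
# plus design row indices i1,i2 (NA when the member is absent).
pair_table <- function(x, measure, phenotype) {
  d <- x$data
  if (!measure %in% names(d)) stop("unknown measure: ", measure)
  pcol <- paste0("affected_", phenotype)
  if (!pcol %in% names(d)) stop("unknown phenotype: ", phenotype)
  if (nrow(d) == 0L)
    return(data.frame(pair_id = character(0), zyg = character(0),
                      y1 = numeric(0), y2 = numeric(0),
                      d1 = numeric(0), d2 = numeric(0),
                      i1 = integer(0), i2 = integer(0)))
  i1 <- match(paste(unique(d$pair_id), 1), paste(d$pair_id, d$member_index))
  i2 <- match(paste(unique(d$pair_id), 2), paste(d$pair_id, d$member_index))
  pid <- unique(d$pair_id)
  zyg <- d$zygosity[ifelse(is.na(i1), i2, i1)]
  out <- data.frame(
    pair_id = pid, zyg = zyg,
    y1 = ifelse(is.na(i1), NA_real_, d[[measure]][i1]),
    y2 = ifelse(is.na(i2), NA_real_, d[[measure]][i2]),
    d1 = ifelse(is.na(i1), NA_real_, d[[pcol]][i1]),
    d2 = ifelse(is.na(i2), NA_real_, d[[pcol]][i2]),
    i1 = i1, i2 = i2,
    stringsAsFactors = FALSE
  )
  usable <- !is.na(out$y1) | !is.na(out$y2) | !is.na(out$d1) | !is.na(out$d2)
  out[usable, , drop = FALSE]
}
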