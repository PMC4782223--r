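#' Helmert contrast matrix for the five sentence regions
#'
#' Each of the four contrasts compares one region with the average of the
#' regions preceding it: critical1 vs. precritical, critical2 vs. the mean
#' of the first two, spillover1 vs. the mean of the first three, and
#' spillover2 vs. the mean of the first four. Columns are pairwise
#' orthogonal and sum to zero.
#'
#' @return A 5 x 4 numeric matrix with regions as rownames.
#' @export
helmert_regions <- function() {
  m <- matrix(c(
    -1, -1, -1, -1,
     1, -1, -1, -1,
     0,  2, -1, -1,
     0,  0,  3, -1,
     0,  0,  0,  4
  ), nrow = 5, byrow = TRUE,
  dimnames = list(.regions, paste0("region_c", 1:4)))
  m
}

#' Build model matrices for the reading-time analysis
#'
#' Assembles the fixed-effect design and random-effect grouping indices
#' from a trial table: sum-coded length and dependency factors (-1/+1),
#' scaled and centered WMC and reading-fluency covariates, Helmert region
#' contrasts ([helmert_regions()]) when more than one region is present,
#' and the locality interactions up to
#' `length:dependency:covariate`.
#'
#' @param records Trial table (see [generate_dataset()]) with columns
#'   `participant`, `item`, `sentence`, `region`, `length`, `dependency`,
#'   `wmc_score`, `rf_score`, `rt_ms`.
#' @param regions Regions to include; default all present. Passing a
#'   single region yields a nested per-region design without region
#'   contrasts.
#' @return A list of class `rt_design`: `X` (fixed-effect matrix with an
#'   `(Intercept)` column), `groups` (integer indices for `participant`,
#'   `item`, `sentence`), `y` (RTs in ms), `records` (the rows used), and
#'   `scaling` (centers/scales of the covariates).
#' @export
build_design <- function(records, regions = NULL) {
  req <- c("participant", "item", "sentence", "region", "length",
           "dependency", "wmc_score", "rf_score", "rt_ms")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reg <- as.character(records$region)
  unknown <- setdiff(unique(reg), .regions)
  if (length(unknown)) {
    stop("unknown region label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(regions)) {
    bad <- setdiff(regions, .regions)
    if (length(bad)) {
      stop("unknown region label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    records <- records[reg %in% regions, , drop = FALSE]
    reg <- as.character(records$region)
  }
  if (!nrow(records)) stop("no records left after region subset",
                           call. = FALSE)
  if (!all(c(-1, 1) %in% records$length) ||
      !all(c(-1, 1) %in% records$dependency)) {
    stop("both levels (-1, +1) of length and dependency must be present",
         call. = FALSE)
  }
  for (v in c("wmc_score", "rf_score")) {
    if (stats::sd(records[[v]]) == 0) {
      stop("covariate ", v, " is constant and cannot be scaled",
           call. = FALSE)
    }
  }
  wmc_c <- mean(records$wmc_score); wmc_s <- stats::sd(records$wmc_score)
  rf_c <- mean(records$rf_score); rf_s <- stats::sd(records$rf_score)
  wmc <- (records$wmc_score - wmc_c) / wmc_s
  rf <- (records$rf_score - rf_c) / rf_s
  len <- records$length
  dep <- records$dependency
  X <- cbind(
    "(Intercept)" = 1,
    length = len,
    dependency = dep,
    wmc = wmc,
    rf = rf,
    "length:dependency" = len * dep,
    "length:dependency:wmc" = len * dep * wmc,
    "length:dependency:rf" = len * dep * rf
  )
  if (length(unique(reg)) > 1) {
    helm <- helmert_regions()
    X <- cbind(X, helm[reg, , drop = FALSE])
  }
  groups <- list(
    participant = as.integer(factor(records$participant)),
    item = as.integer(factor(records$item)),
    sentence = as.integer(factor(records$sentence))
  )
  structure(
    list(X = X, groups = groups, y = records$rt_ms, records = records,
         scaling = list(wmc = c(center = wmc_c, scale = wmc_s),
                        rf = c(center = rf_c, scale = rf_s))),
    class = "rt_design"
  )
}
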