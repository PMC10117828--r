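# Percentile-based Immunoscore from CD3 and CD8 densities in TC and IM.

#' Within-cohort percentile ranks
#'
#' Converts a cohort column of densities into percentiles: `100 * rank / n`
#' with ascending ranks and mid-rank ties, so the cohort maximum maps to 100
#' (default). The alternative Hazen definition `100 * (rank - 0.5) / n` is
#' available via `method`. NAs propagate and do not consume ranks.
#'
#' @param x numeric vector (one cohort column).
#' @param method `"rank"` (default) or `"hazen"`.
#' @return Percentiles in (0, 100].
#' @export
percentile_rank <- function(x, method = c("rank", "hazen")) {
  method <- match.arg(method)
  if (all(is.na(x))) stop("all values missing: cannot rank")
  if (sum(!is.na(x)) < 2) stop("need at least 2 non-missing values to rank")
  n <- sum(!is.na(x))
  r <- rank(x, na.last = "keep", ties.method = "average")
  switch(method, rank = 100 * r / n, hazen = 100 * (r - 0.5) / n)
}

#' Immunoscore from four percentile columns
#'
#' The Immunoscore is the average of the cohort percentiles of four
#' densities: CD3 in TC, CD3 in IM, CD8 in TC, CD8 in IM. The two-category
#' score is `"low"` when the averaged score is in \[0, 25\] (the boundary 25
#' counts as low) and `"high"` above 25. Patients with any missing component
#' get NA score and category.
#'
#' @param densities data frame with columns `cd3_tc`, `cd3_im`, `cd8_tc`,
#'   `cd8_im` (cells/mm^2), one row per patient.
#' @param boundary low/high cut on the averaged score (default 25).
#' @param method percentile definition, see [percentile_rank()].
#' @return Input tibble with `score` (0-100) and `category` (`low`/`high`)
#'   columns appended.
#' @export
immunoscore <- function(densities, boundary = 25, method = "rank") {
  need <- c("cd3_tc", "cd3_im", "cd8_tc", "cd8_im")
  missing_cols <- setdiff(need, names(densities))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  densities <- tibble::as_tibble(densities)
  pct <- purrr::map_dfc(densities[need], percentile_rank, method = method)
  score <- rowMeans(as.matrix(pct))
  dplyr::mutate(densities,
    score = score,
    category = dplyr::if_else(score <= boundary, "low", "high"))
}

#' Append the Immunoscore to a cohort parameter table
#'
#' Fills the `Immunoscore` column of a [quantify_patient()]-shaped cohort
#' table from its CD3/CD8 TC and IM density columns, and adds the
#' two-category label.
#'
#' @param params cohort tibble with columns `TC_CD3`, `IM_CD3`, `TC_CD8`,
#'   `IM_CD8` (one row per patient).
#' @inheritParams immunoscore
#' @return `params` with `Immunoscore` filled and `Immunoscore_category`
#'   appended.
#' @export
add_immunoscore <- function(params, boundary = 25, method = "rank") {
  sc <- immunoscore(
    tibble::tibble(cd3_tc = params$TC_CD3, cd3_im = params$IM_CD3,
                   cd8_tc = params$TC_CD8, cd8_im = params$IM_CD8),
    boundary = boundary, method = method)
  dplyr::mutate(params, Immunoscore = sc$score, Immunoscore_category = sc$category)
}
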