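#' pcSM coefficients
#'
#' Multipliers of the cumulative score
#' `CS = c_A1*A1 + c_A2*A2 + c_A3*A3 + c_A4*A4 + max(c_pH*PH, c_pS*PS) +
#' c_M1*M1`. Defaults are the published optimized values; any subset can
#' be overridden.
#'
#' @param ... Named overrides among `c_A1`, `c_A2`, `c_A3`, `c_A4`,
#'   `c_pH`, `c_pS`, `c_M1`.
#' @return A named numeric vector of the seven coefficients.
#' @export
pcsm_coefficients <- function(...) {
  co <- c(c_A1 = 10, c_A2 = 0.1, c_A3 = 0.00001, c_A4 = 0.001,
          c_pH = 0.15, c_pS = 0.21, c_M1 = 0.001)
  dots <- list(...)
  if (length(dots) > 0) {
    bad <- setdiff(names(dots), names(co))
    if (length(bad) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown coefficient(s): ", paste(bad, collapse = ", ")))
    }
    co[names(dots)] <- as.numeric(unlist(dots))
  }
  co
}

#' Cumulative physico-chemical score (CS)
#'
#' Adds a `CS` column to a descriptor table:
#' `CS = c_A1*A1 + c_A2*A2 + c_A3*A3 + c_A4*A4 + max(c_pH*PH, c_pS*PS) +
#' c_M1*M1`. Each secondary-structure penalty carries its own coefficient
#' and the larger product enters the sum. All six terms are penalty-like,
#' so lower CS indicates a more native-like model.
#'
#' @param descriptors A data frame with columns `A1`, `A2`, `A3`, `A4`,
#'   `PH`, `PS`, `M1` (one row per decoy), e.g. from [describe_pool()].
#' @param coefficients See [pcsm_coefficients()].
#' @return The input with a `CS` column appended (recomputed if present).
#' @export
cumulative_score <- function(descriptors, coefficients = pcsm_coefficients()) {
  need <- c("A1", "A2", "A3", "A4", "PH", "PS", "M1")
  missing_cols <- setdiff(need, names(descriptors))
  if (length(missing_cols) > 0) {
    abort(paste0("descriptor column(s) missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  d <- descriptors[need]
  if (anyNA(d)) abort("descriptor fields must be set (no NA)")
  co <- coefficients
  cs <- co[["c_A1"]] * d$A1 + co[["c_A2"]] * d$A2 + co[["c_A3"]] * d$A3 +
    co[["c_A4"]] * d$A4 + pmax(co[["c_pH"]] * d$PH, co[["c_pS"]] * d$PS) +
    co[["c_M1"]] * d$M1
  out <- as_tibble(descriptors)
  out$CS <- as.numeric(cs)
  out
}

#' Rank decoys by ascending CS
#'
#' Stable sort on CS (lower is better; ties keep input order), truncated
#' to the best `k`.
#'
#' @param descriptors A descriptor table with an `id` column; a `CS`
#'   column is computed if absent.
#' @param k Number of decoys to keep (default 10).
#' @param coefficients See [pcsm_coefficients()].
#' @return A tibble of `(id, CS)` in non-decreasing CS order, at most `k`
#'   rows.
#' @export
rank_decoys <- function(descriptors, k = 10L,
                        coefficients = pcsm_coefficients()) {
  if (!"id" %in% names(descriptors)) abort("descriptor table needs an 'id' column")
  if (!"CS" %in% names(descriptors)) {
    descriptors <- cumulative_score(descriptors, coefficients)
  }
  ord <- order(descriptors$CS)  # stable in R
  out <- as_tibble(descriptors[ord, c("id", "CS")])
  head(out, k)
}
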