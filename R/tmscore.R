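#' Length-dependent TM-score distance scale
#'
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8` for `L > 15`, floored at 0.5 Angstrom
#' (the floor also covers very short chains where the formula goes
#' negative or is undefined).
#'
#' @param L Reference length (residues), `L >= 1`.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L) {
  stopifnot(L >= 1)
  d0 <- ifelse(L > 15, 1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)
  pmax(d0, 0.5)
}

tm_sum <- function(d2, d0) sum(1 / (1 + d2 / d0^2))

#' TM-score of a model against a reference structure
#'
#' Computes the template-modeling score
#' `max (1/L_target) * sum_i 1 / (1 + (d_i/d0)^2)` over searched
#' superpositions, normalized by the reference length. The search seeds
#' superpositions from contiguous fragments of the aligned pairs (lengths
#' `L_aln`, `L_aln/2`, `L_aln/4`, minimum 4) at every start position;
#' each seed is refined by iteratively superposing on the pairs within a
#' distance cutoff (starting at `max(d0 + 1, 4.5)` Angstrom, shrunk by
#' 0.5 Angstrom while fewer than 3 pairs qualify) until the included set
#' reaches a fixed point (at most 20 iterations). The best score seen at
#' any superposition is reported.
#'
#' @param model,reference Structure tibbles with CA atoms.
#' @param mapping Optional residue-pair mapping (model index, reference
#'   index); defaults to the positional identity when the sequences match.
#' @return An object of class `tm_result`: list with `score`, `d0`,
#'   `L_target` (reference residue count used for normalization) and
#'   `n_aligned`.
#' @export
tm_score <- function(model, reference, mapping = NULL) {
  L_target <- n_residues(reference)
  pc <- paired_coords(model, reference, "ca", mapping)
  n_aln <- nrow(pc$a)
  if (n_aln < 3) abort("TM-score needs at least 3 mapped residue pairs")
  d0 <- tm_d0(L_target)

  xm <- pc$a  # model CA, aligned order
  xr <- pc$b  # reference CA

  score_of <- function(idx) {
    # superpose on the subset idx, score all aligned pairs
    fit <- kabsch_cpp(xr[idx, , drop = FALSE], xm[idx, , drop = FALSE])
    moved <- sweep(xm %*% t(fit$rotation), 2, as.vector(fit$translation), `+`)
    rowSums((moved - xr)^2)
  }

  frag_lengths <- unique(pmax(4L, c(n_aln, ceiling(n_aln / 2), ceiling(n_aln / 4))))
  frag_lengths <- frag_lengths[frag_lengths <= n_aln]

  best <- 0
  d_start <- max(d0 + 1, 4.5)
  for (fl in frag_lengths) {
    for (start in seq_len(n_aln - fl + 1)) {
      idx <- start:(start + fl - 1)
      prev <- integer(0)
      for (iter in seq_len(20L)) {
        d2 <- score_of(idx)
        best <- max(best, tm_sum(d2, d0) / L_target)
        cut <- d_start
        repeat {
          inc <- which(d2 < cut^2)
          if (length(inc) >= 3 || cut <= 0.5) break
          cut <- cut - 0.5
        }
        if (length(inc) < 3) break
        if (length(inc) == length(idx) && all(inc == idx)) break
        if (length(inc) == length(prev) && all(inc == prev)) break
        prev <- idx
        idx <- inc
      }
    }
  }

  out <- list(score = best, d0 = d0, L_target = L_target, n_aligned = n_aln)
  class(out) <- "tm_result"
  out
}

#' @export
print.tm_result <- function(x, ...) {
  cat("<TM-score ", format(x$score, digits = 4), " (L_target ", x$L_target,
      ", d0 ", format(x$d0, digits = 4), " A, ", x$n_aligned,
      " aligned)>\n", sep = "")
  invisible(x)
}

#' @export
tidy.tm_result <- function(x, ...) {
  tibble(tm_score = x$score, d0 = x$d0, L_target = x$L_target,
         n_aligned = x$n_aligned)
}
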