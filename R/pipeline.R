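blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

#' Global alignment of model and native sequences
#'
#' Needleman-Wunsch global pairwise alignment (BLOSUM62, affine gaps:
#' open 10, extend 0.5) between the model and native sequences, as used
#' to build the residue correspondence for evaluation. Nonstandard
#' residues appear as `"X"` and score as mismatches.
#'
#' @param model_seq,native_seq 1-letter sequences.
#' @return A tibble of aligned residue pairs (`model_pos`, `native_pos`)
#'   with the alignment `score` in the `"score"` attribute.
#' @export
align_for_eval <- function(model_seq, native_seq) {
  if (nchar(model_seq) == 0 || nchar(native_seq) == 0) {
    abort("sequences must be nonempty")
  }
  aln <- Biostrings::pairwiseAlignment(
    model_seq, native_seq, type = "global",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ip <- cumsum(p != "-")
  is <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  out <- tibble(model_pos = ip[keep], native_pos = is[keep])
  attr(out, "score") <- Biostrings::score(aln)
  out
}

#' Evaluate predictions against a native structure
#'
#' For each model: align the sequences ([align_for_eval()]), drop aligned
#' pairs where either side lacks a C-alpha (residues with missing
#' coordinates are removed so the compared sequences match exactly), then
#' compute the C-alpha RMSD ([rmsd()]) and TM-score ([tm_score()],
#' normalized by the native length) over the mapping.
#'
#' @param predictions A pool tibble of models.
#' @param native A structure tibble with C-alpha coordinates.
#' @return A tibble with `model_id`, `ca_rmsd`, `tm_score`, `n_aligned`,
#'   `L_native`.
#' @export
evaluate <- function(predictions, native) {
  native_seq <- extract_sequence(native)
  model_seq <- pool_sequence(predictions)
  mapping <- align_for_eval(model_seq, native_seq)
  ca_nat <- rownames(ca_coords(native))
  rows <- purrr::map2(predictions$structure, predictions$id, function(m, id) {
    ca_mod <- rownames(ca_coords(m))
    mp <- mapping[as.character(mapping$model_pos) %in% ca_mod &
                    as.character(mapping$native_pos) %in% ca_nat, ]
    if (nrow(mp) < 3) abort(paste0("too few mappable residues for ", id))
    tm <- tm_score(m, native, mapping = mp)
    tibble(model_id = id,
           ca_rmsd = rmsd(m, native, subset = "ca", mapping = mp),
           tm_score = tm$score,
           n_aligned = tm$n_aligned,
           L_native = tm$L_target)
  })
  dplyr::bind_rows(rows)
}

#' Best prediction per target
#'
#' @param records A tibble of evaluation records with a `target` column
#'   (rows from [evaluate()] bound over targets).
#' @return A tibble with one row per target: `best_tm` (max TM-score) and
#'   `best_rmsd` (min C-alpha RMSD) over that target's predictions.
#' @export
best_by_target <- function(records) {
  records |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(best_tm = max(.data$tm_score),
                     best_rmsd = min(.data$ca_rmsd),
                     n_models = dplyr::n(), .groups = "drop")
}

#' Benchmark summary fractions
#'
#' Per target, the best of the (at most five) predictions is taken; the
#' summary reports the fraction of targets whose best TM-score reaches
#' `tm_cut` (inclusive) and whose best C-alpha RMSD is within `rmsd_cut`
#' (inclusive).
#'
#' @inheritParams best_by_target
#' @param tm_cut TM-score threshold (default 0.5, the same-fold
#'   convention).
#' @param rmsd_cut RMSD threshold in Angstrom (default 5.0).
#' @return A one-row tibble: `n_targets`, `frac_tm_ge`, `frac_rmsd_le`.
#' @export
summarize_targets <- function(records, tm_cut = 0.5, rmsd_cut = 5.0) {
  if (nrow(records) == 0) abort("no evaluation records")
  best <- best_by_target(records)
  tibble(n_targets = nrow(best),
         frac_tm_ge = mean(best$best_tm >= tm_cut),
         frac_rmsd_le = mean(best$best_rmsd <= rmsd_cut))
}

#' Staged selection of five candidate structures
#'
#' Runs the full selection protocol on a decoy pool:
#' 1. RMSD-radius clustering ([kclust()]) and representative picking;
#' 2. pcSM ranking of the representatives, keep the top 10;
#' 3. composite-quality ranking of those 10: the top 5 are kept and the
#'    single best is passed to the refinement hook;
#' 4. the refined pool (identity by default: refinement engines are
#'    pluggable) is pcSM-ranked, keep the top 10;
#' 5. stage-4 output is merged with the stage-3 top 5, de-duplicated
#'    by id;
#' 6. the merged set is pcSM re-ranked and the best `min(5, distinct)`
#'    models are emitted.
#'
#' No energy minimization is performed before scoring; the quality table
#' (including the clash report) is attached to the result instead.
#'
#' @param pool A pool tibble.
#' @param predicted_ss Predicted H/E/C string matching the pool sequence
#'   length.
#' @param refine Refinement hook: a function `pool -> pool` preserving
#'   the sequence (default identity).
#' @param radius Clustering radius in Angstrom.
#' @param atom_subset Atom subset for clustering.
#' @param coefficients pcSM coefficients.
#' @param n_points SASA lattice points per atom.
#' @return An object of class `selection_report`: list with `final`
#'   (tibble `id`, `CS`), `stage_trace` (named list of id vectors),
#'   `descriptors` (descriptor + CS table of every scored model),
#'   `quality` (quality table of the pcSM top 10) and `structures`
#'   (named list of the final structures).
#' @export
select_top5 <- function(pool, predicted_ss, refine = identity,
                        radius = 1.0, atom_subset = "heavy",
                        coefficients = pcsm_coefficients(),
                        n_points = 960L) {
  if (nrow(pool) == 0) abort("empty pool")
  predicted_ss <- read_ss(predicted_ss)
  if (nchar(predicted_ss) != nchar(pool_sequence(pool))) {
    abort("predicted secondary structure length must match the pool sequence")
  }

  # (1) cluster and keep one representative per topology
  cs <- kclust(pool, radius = radius, atom_subset = atom_subset)
  reps <- representatives(cs, pool)

  # (2) pcSM rank the representatives
  desc <- cumulative_score(
    describe_pool(reps, predicted_ss, n_points = n_points),
    coefficients
  )
  top10 <- rank_decoys(desc, k = 10L, coefficients = coefficients)
  pool10 <- reps[match(top10$id, reps$id), ]

  # (3) quality-composite ranking of the pcSM top 10
  qual <- quality_pool(pool10)
  q_ord <- qual[order(qual$composite), ]
  q_top5 <- head(q_ord$id, 5L)
  q_top1 <- q_ord$id[1]

  # (4) refinement hook on the best model, pcSM rank of its output
  refine_in <- pool[match(q_top1, pool$id), ]
  attr(refine_in, "sequence") <- pool_sequence(pool)
  class(refine_in) <- class(pool)
  refined <- refine(refine_in)
  if (pool_sequence(refined) != pool_sequence(pool)) {
    abort("refinement hook must preserve the sequence")
  }
  refined_desc <- cumulative_score(
    describe_pool(refined, predicted_ss, n_points = n_points),
    coefficients
  )
  refined_top <- rank_decoys(refined_desc, k = 10L,
                             coefficients = coefficients)

  # (5) merge refined output with the quality top 5, de-duplicate by id
  merged_ids <- unique(c(refined_top$id, q_top5))

  # (6) pcSM re-rank of the merged set
  all_desc <- dplyr::bind_rows(
    refined_desc[match(intersect(refined_top$id, merged_ids),
                       refined_desc$id), ],
    desc[match(setdiff(merged_ids, refined_desc$id), desc$id), ]
  )
  final <- rank_decoys(all_desc, k = 5L, coefficients = coefficients)

  struct_of <- function(id) {
    i <- match(id, refined$id)
    if (!is.na(i)) return(refined$structure[[i]])
    pool$structure[[match(id, pool$id)]]
  }
  out <- list(
    final = final,
    stage_trace = list(
      post_cluster = reps$id,
      pcsm_top10 = top10$id,
      quality_top5 = q_top5,
      refine_input = q_top1,
      refined = refined_top$id,
      merged = merged_ids,
      final = final$id
    ),
    descriptors = dplyr::bind_rows(desc,
                                   refined_desc[!(refined_desc$id %in% desc$id), ]),
    quality = qual,
    structures = setNames(lapply(final$id, struct_of), final$id)
  )
  class(out) <- "selection_report"
  out
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report: ", length(x$stage_trace$post_cluster),
      " representatives -> ", length(x$stage_trace$pcsm_top10),
      " pcSM -> ", length(x$stage_trace$merged), " merged -> ",
      nrow(x$final), " final>\n", sep = "")
  print(x$final)
  invisible(x)
}

#' @export
tidy.selection_report <- function(x, ...) {
  dplyr::mutate(x$final, rank = dplyr::row_number(), .before = 1)
}

#' @export
glance.selection_report <- function(x, ...) {
  tr <- x$stage_trace
  tibble(n_representatives = length(tr$post_cluster),
         n_pcsm_top = length(tr$pcsm_top10),
         n_quality_top = length(tr$quality_top5),
         n_refined = length(tr$refined),
         n_merged = length(tr$merged),
         n_final = nrow(x$final),
         best_cs = min(x$final$CS))
}
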