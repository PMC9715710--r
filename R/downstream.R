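#' Impute genes across datasets
#'
#' Encodes the source cells' common-gene profiles (evaluation mode, no
#' sampling, hence deterministic) and decodes them through the *target*
#' dataset's branches: the common decoder with the target's
#' batch-normalization branch yields the target-conditioned common genes, and
#' the target's specific decoder yields genes measured only in the target
#' dataset. This is how a trained atlas predicts unmeasured genes for new
#' cells — including cells never seen in training ("online" imputation,
#' no retraining needed).
#'
#' @param object A [uotvae()] fit (or `coupled_vae` with gene lists).
#' @param source_matrix Cell-by-common-gene matrix in \[0, 1\]; when `NULL`
#'   and `object` is a fit, the stored training matrix of `source_id`.
#' @param source_id Dataset id of the source cells.
#' @param target_id Registered dataset id whose decoder branches are used.
#' @return `list(common, specific)` of predicted matrices carrying the
#'   target's gene ids.
#' @export
impute <- function(object, source_matrix = NULL, source_id, target_id) {
  model <- as_coupled_vae(object)
  check_dataset_id(model, target_id)
  if (is.null(source_matrix))
    source_matrix <- training_matrix(object, source_id, "common")
  z <- embed_cells(model, source_matrix)
  list(common = decode_common(model, z, target_id),
       specific = decode_specific(model, z, target_id))
}

# internal: column-normalized class mass of a plan
plan_class_probs <- function(plan, source_labels) {
  if (length(source_labels) != nrow(plan))
    stop("length(source_labels) must equal nrow(plan)")
  if (any(plan < 0)) stop("plan entries must be >= 0")
  lab <- factor(source_labels)
  agg <- rowsum(plan, lab)                      # class x target mass
  tot <- colSums(agg)
  probs <- t(agg) / ifelse(tot > 0, tot, 1)     # target x class
  colnames(probs) <- levels(lab)
  rownames(probs) <- if (is.null(colnames(plan)))
    paste0("target", seq_len(ncol(plan))) else colnames(plan)
  list(probs = probs, zero_mass = tot == 0)
}

#' Transfer labels through a transport plan
#'
#' For each target cell (column of the plan), the probability of class `c` is
#' the plan mass arriving from source cells labelled `c`, normalized by the
#' column's total mass. The hard label is the argmax; ties go to the first
#' class in lexicographic order (recorded in the `tied` flag). Columns with
#' zero mass receive `NA`.
#'
#' @param plan Non-negative source-by-target plan (e.g. the accumulated
#'   global plan of a [uotvae()] fit).
#' @param source_labels Labels over the plan's rows.
#' @return `list(labels, prob, tied, zero_mass)`: hard labels (character,
#'   `NA` for zero-mass columns), the target-by-class probability matrix, and
#'   per-target flags.
#' @export
label_transfer <- function(plan, source_labels) {
  pc <- plan_class_probs(plan, source_labels)
  probs <- pc$probs
  hard <- colnames(probs)[apply(probs, 1, which.max)]
  tied <- apply(probs, 1, function(p) sum(p == max(p)) > 1)
  hard[pc$zero_mass] <- NA_character_
  list(labels = hard, prob = probs, tied = tied, zero_mass = pc$zero_mass)
}

#' Deconvolute spots into cell-type proportions
#'
#' Identical computation to [label_transfer()]'s probability vectors, viewed
#' as spot compositions: plan columns are spatial spots, and each spot's
#' proportion of cell type `c` is the column-normalized mass received from
#' source cells of type `c`. Invariant to global rescaling of the plan.
#'
#' @param plan Non-negative cell-by-spot transport plan.
#' @param source_labels Cell-type labels over the plan's rows.
#' @return An object of class `deconvolution_result`: `proportions`
#'   (spot-by-celltype matrix, rows summing to 1), `celltypes`, `spot_ids`
#'   and a `zero_mass` flag for spots that received no mass (their rows are
#'   left at zero).
#' @export
deconvolute <- function(plan, source_labels) {
  pc <- plan_class_probs(plan, source_labels)
  structure(list(proportions = pc$probs,
                 celltypes = colnames(pc$probs),
                 spot_ids = rownames(pc$probs),
                 zero_mass = pc$zero_mass),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> %d spots x %d cell types (%d zero-mass)\n",
              nrow(x$proportions), ncol(x$proportions), sum(x$zero_mass)))
  invisible(x)
}

#' Tertiary lymphoid structure score
#'
#' Per spot, the summed proportion of T cells and B cells, with a
#' colocalization flag set when both proportions individually exceed `floor`.
#' High-scoring colocalized spots are candidate TLS locations.
#'
#' @param result A [deconvolute()] result.
#' @param t_cell_label,b_cell_label Cell-type labels of the T- and B-cell
#'   populations (must be present in the result).
#' @param floor Minimum per-type proportion for colocalization (default
#'   0.05).
#' @return A data frame with columns `spot`, `score` and `colocalized`.
#' @export
tls_score <- function(result, t_cell_label, b_cell_label, floor = 0.05) {
  stopifnot(inherits(result, "deconvolution_result"))
  for (lab in c(t_cell_label, b_cell_label))
    if (!lab %in% result$celltypes)
      stop("cell type '", lab, "' not present in the deconvolution result")
  pt <- result$proportions[, t_cell_label]
  pb <- result$proportions[, b_cell_label]
  data.frame(spot = result$spot_ids,
             score = pt + pb,
             colocalized = pt > floor & pb > floor,
             row.names = NULL)
}

#' Write deconvolution proportions to CSV
#'
#' @param result A [deconvolute()] result.
#' @param path Output CSV path (spots in rows, cell types in columns).
#' @return `path`, invisibly.
#' @export
write_proportions <- function(result, path) {
  stopifnot(inherits(result, "deconvolution_result"))
  df <- data.frame(spot = result$spot_ids, result$proportions,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
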