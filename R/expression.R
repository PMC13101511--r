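#' Relative expression by the 2^-ddCt (Livak) method
#'
#' From a tidy table of qPCR cycle-threshold values, computes per-gene,
#' per-condition fold changes relative to a control condition, normalised to
#' an internal reference gene. Aggregation order follows the Livak
#' convention: technical replicates are averaged to one Ct per (gene,
#' condition, biological replicate); dCt = Ct_gene - Ct_reference within
#' each (condition, bio-rep); ddCt = dCt - mean(dCt in the control
#' condition); per-rep fold change 2^-ddCt is then averaged over biological
#' replicates, with its SD reported. The reference gene's own fold change is
#' 1.0 in every condition by construction, and all fold changes are
#' invariant to adding a constant to every Ct in a (condition, bio-rep)
#' stratum.
#'
#' @param records data.frame with columns \code{gene}, \code{condition},
#'   \code{bio_rep}, \code{tech_rep}, \code{ct}.
#' @param reference_gene Internal reference gene label (default
#'   \code{"16S"}).
#' @param control_condition Baseline condition (default \code{"glucose"},
#'   the typical non-inducing carbon source).
#' @return data.frame with \code{gene}, \code{condition}, \code{fold_change}
#'   (mean over bio-reps of 2^-ddCt), \code{fold_sd},
#'   \code{log2_fold_change} and \code{n_bio}.
#' @examples
#' ct <- simulate_ct_table(c(nidA = 4, ref = 1), conditions = "pyrene",
#'                         reference_gene = "ref", ct_noise = 0, seed = 1)
#' delta_delta_ct(ct, reference_gene = "ref", control_condition = "control")
#' @export
delta_delta_ct <- function(records, reference_gene = "16S",
                           control_condition = "glucose") {
  need <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("delta_delta_ct: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(records$ct))) {
    stop("delta_delta_ct: all Ct values must be finite")
  }
  if (!control_condition %in% records$condition) {
    stop("delta_delta_ct: control condition '", control_condition,
         "' absent from the table")
  }
  # technical-replicate means
  ctm <- stats::aggregate(ct ~ gene + condition + bio_rep, data = records,
                          FUN = mean)
  strata <- unique(ctm[, c("condition", "bio_rep")])
  ref <- ctm[ctm$gene == reference_gene, , drop = FALSE]
  key <- function(d) paste(d$condition, d$bio_rep, sep = "\r")
  ref_idx <- match(key(ctm), key(ref))
  if (any(is.na(ref_idx))) {
    bad <- unique(key(ctm)[is.na(ref_idx)])
    stop("delta_delta_ct: reference gene '", reference_gene,
         "' missing in stratum (condition, bio_rep): ",
         paste(gsub("\r", ", ", bad), collapse = "; "))
  }
  ctm$d_ct <- ctm$ct - ref$ct[ref_idx]
  # mean control dCt per gene
  ctrl <- ctm[ctm$condition == control_condition, , drop = FALSE]
  ctrl_mean <- stats::aggregate(d_ct ~ gene, data = ctrl, FUN = mean)
  cm_idx <- match(ctm$gene, ctrl_mean$gene)
  if (any(is.na(cm_idx))) {
    stop("delta_delta_ct: gene(s) absent from the control condition: ",
         paste(unique(ctm$gene[is.na(cm_idx)]), collapse = ", "))
  }
  ctm$dd_ct <- ctm$d_ct - ctrl_mean$d_ct[cm_idx]
  ctm$fold <- 2^(-ctm$dd_ct)
  agg <- stats::aggregate(fold ~ gene + condition, data = ctm,
                          FUN = function(x) c(mean = mean(x),
                                              sd = if (length(x) > 1) stats::sd(x) else 0,
                                              n = length(x)))
  out <- data.frame(
    gene = agg$gene,
    condition = agg$condition,
    fold_change = agg$fold[, "mean"],
    fold_sd = agg$fold[, "sd"],
    n_bio = as.integer(agg$fold[, "n"]),
    stringsAsFactors = FALSE
  )
  out$log2_fold_change <- log2(out$fold_change)
  out <- out[order(out$gene, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Flag genes exceeding a fold-change threshold
#'
#' Marks rows of a \code{\link{delta_delta_ct}} result whose mean fold
#' change exceeds \code{threshold_fold} (default 2, the conventional
#' "more than twofold up" call). No statistical test is applied.
#'
#' @param rel A relative-expression data.frame from
#'   \code{\link{delta_delta_ct}}.
#' @param threshold_fold Fold-change threshold (default 2).
#' @return \code{rel} with an added logical column \code{called}.
#' @export
expression_call <- function(rel, threshold_fold = 2) {
  if (!"fold_change" %in% names(rel)) {
    stop("expression_call: expected a delta_delta_ct result")
  }
  rel$called <- rel$fold_change > threshold_fold
  rel
}

#' Read a tidy Ct CSV
#'
#' Columns: \code{gene,condition,bio_rep,tech_rep,ct}.
#' @param path Path to the CSV.
#' @return data.frame of Ct records.
#' @export
read_ct_csv <- function(path) {
  if (!file.exists(path)) stop("read_ct_csv: no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("read_ct_csv: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(tab$ct)) stop("read_ct_csv: ct column must be numeric")
  tab
}
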