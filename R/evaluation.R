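#' @include partial-alignment.R
NULL

#' Read a ground-truth correspondence file
#'
#' CSV with columns `sample_id`, `peak_id` (input-row index within that
#' sample's peak list) and `compound_id`.
#' @param path CSV path.
#' @return data.frame.
#' @export
readGroundTruth <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "peak_id", "compound_id")
    if (!all(need %in% names(df)))
        stop("ground truth lacks columns: ",
             paste(setdiff(need, names(df)), collapse = ", "))
    df$peak_id <- as.integer(df$peak_id)
    df
}

#' Score an alignment table against ground truth
#'
#' A compound present in every sample is a positive peak pair; table rows
#' covering every sample are matched peak pairs. A full row counts as a
#' true positive if all its member peaks trace back (through their source
#' rows) to one and the same positive compound not already credited;
#' every other full row is a false positive, so `FP = Nm - TP` and
#' `FN = Np - TP`. `TPR = TP/(TP+FN)`, `PPV = TP/(TP+FP)` and
#' `F1 = 2*TPR*PPV/(TPR+PPV)`, each defined as 0 when its denominator is
#' 0. Rows not covering all samples are excluded from the bookkeeping and
#' reported as `partialRows`.
#'
#' @param table an [AlignmentTable-class].
#' @param truth data.frame as from [readGroundTruth()].
#' @return an [EvaluationResult-class].
#' @export
scoreAlignment <- function(table, truth) {
    stopifnot(is(table, "AlignmentTable"))
    key <- paste(truth$sample_id, truth$peak_id, sep = "\r")
    if (anyDuplicated(key)) stop("ground truth has duplicate peak ids")
    lookup <- stats::setNames(as.character(truth$compound_id), key)
    samples <- table@samples
    ## positives: compounds with a peak in every sample
    present <- unique(truth[truth$sample_id %in% samples,
                            c("sample_id", "compound_id")])
    cnt <- table(present$compound_id)
    positives <- names(cnt)[as.integer(cnt) == length(samples)]
    np <- length(positives)
    full <- fullRows(table)
    nm <- length(full)
    m <- table@members
    tp <- 0L
    credited <- character()
    for (g in full) {
        rows <- which(m$group_id == g)
        comp <- unique(unlist(lapply(rows, function(r) {
            k <- paste(m$sample_id[r], table@memberSources[[r]], sep = "\r")
            if (any(!k %in% names(lookup)))
                stop("peak id absent from ground truth (sample '",
                     m$sample_id[r], "')")
            unique(lookup[k])
        })))
        if (length(comp) == 1L && comp %in% positives &&
            !comp %in% credited) {
            tp <- tp + 1L
            credited <- c(credited, comp)
        }
    }
    fp <- nm - tp
    fn <- np - tp
    tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
    ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (tpr + ppv > 0) 2 * tpr * ppv / (tpr + ppv) else 0
    new("EvaluationResult", np = as.integer(np), nm = as.integer(nm),
        tp = tp, fp = as.integer(fp), fn = as.integer(fn),
        tpr = tpr, ppv = ppv, f1 = f1,
        partialRows = as.integer(nrow(table@groups) - nm))
}
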