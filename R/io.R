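#' @include accessors.R
NULL

#' Parse a serialized fragment spectrum
#'
#' Parses the peak-list dialect's spectrum field: whitespace-separated
#' `mz:intensity` tokens, e.g. `"73:999 147:500"`. m/z values are rounded
#' to the nearest integer channel by default and intensities on duplicate
#' channels are summed; output is sorted by m/z.
#'
#' @param text character(1) spectrum string.
#' @param roundMz round m/z to unit resolution (default TRUE).
#' @return a [MassSpectrum-class]
#' @examples
#' parseSpectrum("147:500 73:999")
#' @export
parseSpectrum <- function(text, roundMz = TRUE) {
    if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
        stop("malformed spectrum: empty or blank text")
    tok <- strsplit(trimws(text), "[[:space:]]+")[[1]]
    parts <- strsplit(tok, ":", fixed = TRUE)
    if (any(lengths(parts) != 2L))
        stop("malformed spectrum: token(s) not of the form mz:intensity in '",
             substr(text, 1, 40), "'")
    m <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    i <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    if (any(is.na(m)) || any(is.na(i)))
        stop("malformed spectrum: non-numeric token in '",
             substr(text, 1, 40), "'")
    MassSpectrum(m, i, roundMz = roundMz)
}

#' Serialize a spectrum to the dialect string
#' @param x a [MassSpectrum-class]
#' @return character(1) of `mz:intensity` tokens
#' @export
formatSpectrum <- function(x) {
    paste(sprintf("%g:%g", x@mz, x@intensity), collapse = " ")
}

#' Default input column mapping
#'
#' The reader's defaults match a common ChromaTOF-style export: `Name`,
#' a combined retention-time column `R.T. (s)` holding `"rt1 , rt2"` in
#' seconds, `Area`, and `Spectrum` (space-separated `mz:intensity`).
#' @return named list of column names and the field separator (`NA` =
#'   sniff comma vs tab from the header line).
#' @export
peakListDialect <- function() {
    list(name = "Name", rt = "R.T. (s)", area = "Area",
         spectrum = "Spectrum", sep = NA_character_)
}

#' Read one sample's peak list
#'
#' Reads a delimited ChromaTOF-style peak list. Rows with non-positive
#' area or retention time, or an unparseable spectrum, are rejected with a
#' warning naming the row; a missing required column is an error.
#'
#' @param path file path.
#' @param sampleId sample identifier; default: file base name.
#' @param dialect column mapping, see [peakListDialect()].
#' @param roundMz round spectrum m/z to unit resolution (default TRUE).
#' @return a [PeakList-class] sorted by (rt1, rt2).
#' @export
readPeakList <- function(path, sampleId = NULL, dialect = peakListDialect(),
                         roundMz = TRUE) {
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]*$", "", basename(path))
    sep <- dialect$sep
    if (is.na(sep)) {
        hdr <- readLines(path, n = 1L)
        sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
    }
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "", colClasses = "character")
    need <- c(dialect$name, dialect$rt, dialect$area, dialect$spectrum)
    if (!all(need %in% names(df)))
        stop("peak list '", path, "' lacks required column(s): ",
             paste(setdiff(need, names(df)), collapse = ", "))
    n <- nrow(df)
    rtRaw <- strsplit(df[[dialect$rt]], ",", fixed = TRUE)
    bad2 <- lengths(rtRaw) != 2L
    rt1 <- rt2 <- rep(NA_real_, n)
    ok2 <- which(!bad2)
    rt1[ok2] <- suppressWarnings(
        as.numeric(trimws(vapply(rtRaw[ok2], `[`, "", 1L))))
    rt2[ok2] <- suppressWarnings(
        as.numeric(trimws(vapply(rtRaw[ok2], `[`, "", 2L))))
    area <- suppressWarnings(as.numeric(df[[dialect$area]]))
    specTxt <- df[[dialect$spectrum]]
    specs <- vector("list", n)
    reason <- rep(NA_character_, n)
    for (r in seq_len(n)) {
        if (is.na(rt1[r]) || is.na(rt2[r])) { reason[r] <- "bad RT"; next }
        if (rt1[r] <= 0 || rt2[r] <= 0) { reason[r] <- "non-positive RT"; next }
        if (is.na(area[r]) || area[r] <= 0) {
            reason[r] <- "non-positive area"; next
        }
        sp <- tryCatch(parseSpectrum(specTxt[r], roundMz = roundMz),
                       error = function(e) NULL)
        if (is.null(sp)) { reason[r] <- "malformed spectrum"; next }
        specs[[r]] <- sp
    }
    rej <- which(!is.na(reason))
    if (length(rej))
        warning("'", sampleId, "': rejected ", length(rej), " row(s): ",
                paste(sprintf("row %d (%s)", rej, reason[rej]),
                      collapse = "; "))
    keep <- setdiff(seq_len(n), rej)
    PeakList(sampleId,
             data.frame(name = trimws(df[[dialect$name]][keep]),
                        rt1 = rt1[keep], rt2 = rt2[keep], area = area[keep],
                        stringsAsFactors = FALSE),
             specs[keep], sourceIds = as.list(keep))
}

#' Write one sample's peak list in the input dialect
#'
#' @param x a [PeakList-class]
#' @param path output file path.
#' @param dialect column mapping, see [peakListDialect()] (`sep` NA writes
#'   CSV).
#' @export
writePeakList <- function(x, path, dialect = peakListDialect()) {
    stopifnot(is(x, "PeakList"))
    sep <- if (is.na(dialect$sep)) "," else dialect$sep
    p <- x@peaks
    out <- data.frame(a = p$name,
                      b = sprintf("%g , %g", p$rt1, p$rt2),
                      c = sprintf("%.6g", p$area),
                      d = vapply(x@spectra, formatSpectrum, ""),
                      stringsAsFactors = FALSE)
    names(out) <- c(dialect$name, dialect$rt, dialect$area, dialect$spectrum)
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       qmethod = "double")
    invisible(path)
}

#' Write an alignment table
#'
#' CSV with columns `group_id`, `kind`, `consensus_name`, then a
#' `<sid>_rt1`, `<sid>_rt2`, `<sid>_area` triplet per sample; cells of
#' absent members are empty. Reading the file back with
#' [readAlignmentTable()] reproduces the row/column structure and the
#' printed cell values.
#'
#' @param table an [AlignmentTable-class]
#' @param path output CSV path.
#' @export
writeAlignmentTable <- function(table, path) {
    stopifnot(is(table, "AlignmentTable"))
    validObject(table)
    g <- table@groups; m <- table@members
    out <- data.frame(group_id = g$group_id, kind = g$kind,
                      consensus_name = g$consensus_name,
                      stringsAsFactors = FALSE)
    for (sid in table@samples) {
        sel <- m[m$sample_id == sid, , drop = FALSE]
        idx <- match(g$group_id, sel$group_id)
        fmt <- function(v) ifelse(is.na(idx), "", sprintf("%.6f", v[idx]))
        out[[paste0(sid, "_rt1")]] <- fmt(sel$rt1)
        out[[paste0(sid, "_rt2")]] <- fmt(sel$rt2)
        out[[paste0(sid, "_area")]] <- fmt(sel$area)
    }
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Read an alignment table written by [writeAlignmentTable()]
#'
#' Member names and peak indices are not serialized; read-back members
#' carry empty names and sequential indices, sufficient for structural
#' round-trips and downstream reporting.
#'
#' @param path CSV path.
#' @return an [AlignmentTable-class]
#' @export
readAlignmentTable <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
    fixed <- c("group_id", "kind", "consensus_name")
    if (!all(fixed %in% names(df)))
        stop("alignment table lacks required columns")
    sidCols <- grep("_rt1$", names(df), value = TRUE)
    samples <- sub("_rt1$", "", sidCols)
    mem <- list(); src <- list(); k <- 0L
    for (sid in samples) {
        present <- nzchar(df[[paste0(sid, "_rt1")]])
        if (!any(present)) next
        mem[[sid]] <- data.frame(
            group_id = as.integer(df$group_id[present]),
            sample_id = sid,
            peak_idx = seq_len(sum(present)),
            name = "",
            rt1 = as.numeric(df[[paste0(sid, "_rt1")]][present]),
            rt2 = as.numeric(df[[paste0(sid, "_rt2")]][present]),
            area = as.numeric(df[[paste0(sid, "_area")]][present]),
            stringsAsFactors = FALSE)
    }
    m <- if (length(mem)) do.call(rbind, mem) else
        data.frame(group_id = integer(), sample_id = character(),
                   peak_idx = integer(), name = character(),
                   rt1 = numeric(), rt2 = numeric(), area = numeric())
    rownames(m) <- NULL
    new("AlignmentTable", samples = samples,
        groups = data.frame(group_id = as.integer(df$group_id),
                            kind = df$kind,
                            consensus_name = df$consensus_name,
                            stringsAsFactors = FALSE),
        members = m, memberSources = rep(list(integer()), nrow(m)))
}
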