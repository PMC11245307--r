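## AlignmentRecord tables: one row per mapping of one read, with columns
##   read_id, target, start, end (0-based half-open), strand (+/-),
##   mismatches, n_best_hits, read_length.
## This is the common currency of every counting stage.

ALN_COLS <- c("read_id", "target", "start", "end", "strand",
              "mismatches", "n_best_hits", "read_length")

#' Validate (and complete) an alignment table
#'
#' @param df Data frame with at least `read_id`, `target`, `start`, `end`,
#'   `strand`; `mismatches` defaults to 0, `read_length` to `end - start`,
#'   and `n_best_hits` is computed by grouping rows by `read_id` when
#'   absent.
#' @return A validated alignment table with the canonical columns.
#' @export
as_alignments <- function(df) {
  need <- c("read_id", "target", "start", "end", "strand")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("alignment table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) && any(df$end <= df$start)) {
    stop("alignment intervals must satisfy end > start")
  }
  if (is.null(df$mismatches)) df$mismatches <- rep(0L, nrow(df))
  if (is.null(df$read_length)) df$read_length <- df$end - df$start
  if (is.null(df$n_best_hits)) {
    df$n_best_hits <- as.integer(table(df$read_id)[df$read_id])
  }
  stopifnot(all(df$n_best_hits >= 1L),
            all(df$strand %in% c("+", "-")))
  rownames(df) <- NULL
  df[, ALN_COLS]
}

## Reference-consumed width of a CIGAR string (M, D, N, =, X operations).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
    sum(lens[grepl("[MDN=X]", ops)])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignments from SAM or BAM
#'
#' SAM files are converted on the fly with [Rsamtools::asBam()]. Hit
#' multiplicity is taken from the `NH` tag when present, otherwise computed
#' by grouping records by read name (which reproduces an all-best-stratum
#' aligner report). Unmapped records are dropped.
#'
#' @param path Path to a `.sam` or `.bam` file, or an alignment data frame
#'   (returned unchanged after validation).
#' @return An alignment table (see [as_alignments()]).
#' @export
read_alignments <- function(path) {
  if (is.data.frame(path)) return(as_alignments(path))
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "cigar", "qwidth"),
    tag = c("NM", "NH"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (!length(res$qname)) {
    return(as_alignments(data.frame(read_id = character(),
                                    target = character(),
                                    start = integer(), end = integer(),
                                    strand = character(),
                                    stringsAsFactors = FALSE)[0, ]))
  }
  refw <- cigar_ref_width(res$cigar)
  refw[is.na(refw)] <- res$qwidth[is.na(refw)]
  df <- data.frame(
    read_id = res$qname,
    target = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + refw,
    strand = as.character(res$strand),
    mismatches = if (!is.null(res$tag$NM)) {
      m <- res$tag$NM; m[is.na(m)] <- 0L; m
    } else 0L,
    read_length = res$qwidth,
    stringsAsFactors = FALSE)
  if (!is.null(res$tag$NH) && !all(is.na(res$tag$NH))) {
    df$n_best_hits <- res$tag$NH
  }
  as_alignments(df)
}

#' Write an alignment table as SAM
#'
#' Emits a minimal, valid SAM file: `@SQ` header lines from `target_sizes`,
#' one record per row with flag 0/16, an ungapped CIGAR of the read length,
#' and `NM`/`NH` tags carrying mismatches and hit multiplicity.
#'
#' @param aln Alignment table.
#' @param target_sizes Named vector of reference lengths.
#' @param path Output path (`.sam`).
#' @export
write_sam <- function(aln, target_sizes, path) {
  aln <- as_alignments(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(target_sizes),
                     as.integer(target_sizes)), con)
  if (nrow(aln)) {
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    recs <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d\tNH:i:%d",
                    aln$read_id, flag, aln$target, aln$start + 1L,
                    aln$end - aln$start, aln$mismatches, aln$n_best_hits)
    writeLines(recs, con)
  }
  invisible(path)
}
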