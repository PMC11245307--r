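#' Build a subfamily-labeled protein alignment
#'
#' @param sequences Named character vector of aligned residue strings
#'   (equal length; gap character `-` or `.`), or an `AAStringSet`.
#' @param labels Named character vector mapping sequence id to subfamily.
#' @param focal Focal subfamily name (e.g. `"Rhino"`); must be a proper,
#'   non-empty subset of the sequences.
#' @return An object of class `subfamily_msa`.
#' @export
subfamily_msa <- function(sequences, labels, focal) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  sequences <- toupper(gsub("\\.", "-", sequences))
  widths <- nchar(sequences)
  if (!length(sequences)) stop("empty alignment")
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths")
  }
  labels <- labels[names(sequences)]
  if (anyNA(labels)) stop("every sequence needs a subfamily label")
  n_focal <- sum(labels == focal)
  if (n_focal == 0L || n_focal == length(sequences)) {
    stop("focal subfamily must be a non-empty proper subset of sequences")
  }
  structure(list(sequences = sequences, labels = labels, focal = focal,
                 width = widths[1]),
            class = "subfamily_msa")
}

#' Read an aligned FASTA plus a subfamily label table
#'
#' @param fasta Aligned FASTA path.
#' @param labels_tsv Two-column TSV (sequence id, subfamily), no header.
#' @param focal Focal subfamily name.
#' @return A `subfamily_msa`.
#' @export
read_subfamily_msa <- function(fasta, labels_tsv, focal) {
  seqs <- Biostrings::readAAStringSet(fasta)
  lab <- read.table(labels_tsv, sep = "\t", header = FALSE,
                    col.names = c("id", "subfamily"),
                    stringsAsFactors = FALSE)
  subfamily_msa(seqs, setNames(lab$subfamily, lab$id), focal)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$sequences, ""))
}

#' Remove poorly covered alignment columns
#'
#' A column is kept iff the fraction of non-gap rows is at least
#' `min_coverage` (inclusive).
#'
#' @param msa A `subfamily_msa`.
#' @param min_coverage Minimum non-gap fraction in (0, 1]; default 0.70.
#' @return List with `msa` (condensed) and `col_map` (integer vector:
#'   for each kept column, its 0-based index in the original alignment).
#' @export
condense_alignment <- function(msa, min_coverage = 0.70) {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  m <- msa_matrix(msa)
  if (!ncol(m)) stop("empty alignment")
  cover <- colMeans(m != "-")
  keep <- which(cover >= min_coverage)
  seqs <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  out <- msa
  out$sequences <- setNames(seqs, names(msa$sequences))
  out$width <- length(keep)
  list(msa = out, col_map = keep - 1L)
}

#' Score columns for subfamily discrimination
#'
#' Per column, the focal consensus is the modal non-gap residue among
#' focal rows (ties broken alphabetically); its frequency among focal rows
#' and among the remaining rows (gaps counting in both denominators) gives
#' the frequency-contrast score `focal_freq - other_freq` in [-1, 1]. A
#' score of 1 marks a fully discriminative column such as the aspartate to
#' glycine change distinguishing Rhino from other HP1 proteins. Columns
#' where no focal row has a residue are reported with `NA`.
#'
#' @param msa A `subfamily_msa`.
#' @return Data frame `(column, focal_consensus, focal_freq, other_freq,
#'   score)` with `column` 0-based.
#' @export
column_discrimination <- function(msa) {
  m <- msa_matrix(msa)
  is_focal <- msa$labels == msa$focal
  fm <- m[is_focal, , drop = FALSE]
  om <- m[!is_focal, , drop = FALSE]
  n_f <- nrow(fm); n_o <- nrow(om)
  res <- lapply(seq_len(ncol(m)), function(j) {
    col_f <- fm[, j]
    resid <- col_f[col_f != "-"]
    if (!length(resid)) {
      return(data.frame(column = j - 1L, focal_consensus = NA_character_,
                        focal_freq = NA_real_, other_freq = NA_real_,
                        score = NA_real_, stringsAsFactors = FALSE))
    }
    tab <- table(resid)
    cons <- sort(names(tab)[tab == max(tab)])[1]
    ff <- sum(col_f == cons) / n_f
    of <- sum(om[, j] == cons) / n_o
    data.frame(column = j - 1L, focal_consensus = cons,
               focal_freq = ff, other_freq = of, score = ff - of,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Detect subfamily-specific insertions and deletions
#'
#' Flags columns occupied almost exclusively by the focal subfamily
#' (`insertion`, the glycine-insertion signature of Rhino) or almost
#' exclusively by the other subfamilies (`deletion`).
#'
#' @param msa A `subfamily_msa`.
#' @param min_focal_occupancy Minimum non-gap fraction among focal rows.
#' @param max_other_occupancy Maximum non-gap fraction among other rows.
#' @return Data frame `(column, type, focal_occupancy, other_occupancy)`,
#'   `column` 0-based, `type` in `insertion`, `deletion`.
#' @export
find_subfamily_indels <- function(msa, min_focal_occupancy = 0.9,
                                  max_other_occupancy = 0.1) {
  stopifnot(min_focal_occupancy >= 0, min_focal_occupancy <= 1,
            max_other_occupancy >= 0, max_other_occupancy <= 1)
  m <- msa_matrix(msa)
  is_focal <- msa$labels == msa$focal
  occ_f <- colMeans(m[is_focal, , drop = FALSE] != "-")
  occ_o <- colMeans(m[!is_focal, , drop = FALSE] != "-")
  ins <- occ_f >= min_focal_occupancy & occ_o <= max_other_occupancy
  del <- occ_o >= min_focal_occupancy & occ_f <= max_other_occupancy
  data.frame(column = c(which(ins), which(del)) - 1L,
             type = c(rep("insertion", sum(ins)), rep("deletion", sum(del))),
             focal_occupancy = c(occ_f[ins], occ_f[del]),
             other_occupancy = c(occ_o[ins], occ_o[del]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map alignment columns to residue numbers of a reference sequence
#'
#' @param msa A `subfamily_msa`.
#' @param ref_id Sequence id whose residue numbering is wanted.
#' @param columns 0-based alignment column indices.
#' @return Integer vector of 1-based residue numbers in the ungapped
#'   reference (NA where the reference has a gap).
#' @export
column_to_residue <- function(msa, ref_id, columns) {
  chars <- strsplit(msa$sequences[[ref_id]], "")[[1]]
  resno <- cumsum(chars != "-")
  resno[chars == "-"] <- NA_integer_
  resno[columns + 1L]
}
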