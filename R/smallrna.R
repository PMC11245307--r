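#' Small-RNA adapter architecture
#'
#' Describes the cloning layout of a raw read: four random nucleotides at
#' the 5' end, the insert, six random nucleotides, a 5 nt barcode, then the
#' constant 3' linker.
#'
#' @param linker3 Constant 3' adapter sequence (non-empty).
#' @param random3 Random bases between insert and barcode.
#' @param barcode_len Barcode length.
#' @param random5 Random bases at the read 5' end.
#' @param max_linker_mismatches Mismatches tolerated when locating the
#'   linker.
#' @param min_insert Minimum insert length after trimming.
#' @return An object of class `adapter_scheme`.
#' @export
adapter_scheme <- function(linker3 = "TGGAATTCTCGGGTGCCAAGG",
                           random3 = 6L, barcode_len = 5L, random5 = 4L,
                           max_linker_mismatches = 1L, min_insert = 18L) {
  stopifnot(nchar(linker3) > 0, random3 >= 0, barcode_len >= 0,
            random5 >= 0, max_linker_mismatches >= 0, min_insert >= 0)
  structure(list(linker3 = toupper(linker3), random3 = as.integer(random3),
                 barcode_len = as.integer(barcode_len),
                 random5 = as.integer(random5),
                 max_linker_mismatches = as.integer(max_linker_mismatches),
                 min_insert = as.integer(min_insert)),
            class = "adapter_scheme")
}

#' Read (and validate) a FASTQ file
#'
#' Plain or gzip-compressed. Structural validation reports the 1-based
#' record number of the first malformed record.
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("malformed FASTQ record ", n %/% 4L + 1L,
         ": truncated record at end of file")
  }
  if (n == 0L) return(setNames(character(), character()))
  idx <- seq.int(1L, n, by = 4L)
  bad_at <- !startsWith(lines[idx], "@")
  bad_plus <- !startsWith(lines[idx + 2L], "+")
  bad_len <- nchar(lines[idx + 1L]) != nchar(lines[idx + 3L])
  bad <- which(bad_at | bad_plus | bad_len)
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path)
  }
  ids <- sub("\\s.*$", "", substring(lines[idx], 2L))
  setNames(toupper(lines[idx + 1L]), ids)
}

#' Write reads as FASTQ (constant quality)
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fastq <- function(seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  out <- as.vector(rbind(paste0("@", names(seqs)), unname(seqs), "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Trim raw small-RNA reads
#'
#' Locates the leftmost occurrence of the constant 3' linker (allowing up
#' to `max_linker_mismatches` mismatches), strips the linker and the
#' random-nucleotide plus barcode bases preceding it (recording the
#' barcode), and strips the 5' random bases. Reads with no linker match are
#' rejected as `no_adapter`; reads whose insert is shorter than
#' `min_insert` as `too_short`.
#'
#' @param seqs Named character vector of raw sequences (see
#'   [read_fastq()]).
#' @param scheme An [adapter_scheme()].
#' @return Data frame `(read_id, insert, barcode, status)` with `status`
#'   one of `ok`, `no_adapter`, `too_short`.
#' @export
trim_reads <- function(seqs, scheme = adapter_scheme()) {
  if (!length(seqs)) {
    return(data.frame(read_id = character(), insert = character(),
                      barcode = character(), status = character(),
                      stringsAsFactors = FALSE))
  }
  ss <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::vmatchPattern(scheme$linker3, ss,
                                 max.mismatch = scheme$max_linker_mismatches,
                                 fixed = TRUE)
  starts <- vapply(Biostrings::startIndex(m), function(s)
    if (is.null(s) || !length(s)) NA_integer_ else min(s), integer(1))
  tail_len <- scheme$random3 + scheme$barcode_len
  insert_end <- starts - tail_len - 1L       # 1-based inclusive
  insert_start <- scheme$random5 + 1L
  ins_len <- insert_end - insert_start + 1L
  status <- rep("ok", length(seqs))
  status[is.na(starts)] <- "no_adapter"
  status[!is.na(starts) & ins_len < scheme$min_insert] <- "too_short"
  ok <- status == "ok"
  insert <- rep(NA_character_, length(seqs))
  barcode <- rep(NA_character_, length(seqs))
  insert[ok] <- substr(seqs[ok], insert_start, insert_end[ok])
  barcode[ok] <- substr(seqs[ok], starts[ok] - scheme$barcode_len,
                        starts[ok] - 1L)
  data.frame(read_id = names(seqs), insert = insert, barcode = barcode,
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

#' Categorize trimmed reads from their genome alignments
#'
#' A read is `filtered_ncrna` if any of its genome hits overlaps an
#' annotated rRNA, tRNA, snRNA or snoRNA locus or lies on the mitochondrial
#' chromosome; otherwise `mirna` if any hit overlaps a miRNA locus;
#' otherwise `pirna_candidate` if its length falls in the configured piRNA
#' window; otherwise `other`. Reads with no genome hit are `other`.
#'
#' @param reads Data frame with `read_id` and `length` (insert length), or
#'   the output of [trim_reads()] (lengths derived from `insert`).
#' @param genome_aln Alignment table of the trimmed reads on the genome.
#' @param annotations Data frame `(chrom, start, end, feature_type)` with
#'   feature types among rRNA, tRNA, snRNA, snoRNA, miRNA.
#' @param mito_chrom Name of the mitochondrial chromosome.
#' @param config A [pipeline_config()].
#' @return Data frame `(read_id, length, category)`.
#' @export
filter_ncrna <- function(reads, genome_aln, annotations,
                         mito_chrom = "chrM", config = pipeline_config()) {
  if (!is.null(reads$insert) && is.null(reads$length)) {
    reads$length <- nchar(reads$insert)
  }
  aln <- read_alignments(genome_aln)
  structural <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  present <- unique(annotations$feature_type)
  absent <- setdiff(structural, present)
  if (length(absent)) {
    warning("annotation category missing, skipped: ",
            paste(absent, collapse = ", "))
  }
  hit_reads_over <- function(types) {
    ann <- annotations[annotations$feature_type %in% types, , drop = FALSE]
    if (!nrow(ann) || !nrow(aln)) return(character())
    gr_a <- intervals_to_granges(aln[, c("target", "start", "end")] |>
                                   setNames(c("chrom", "start", "end")))
    hits <- GenomicRanges::findOverlaps(gr_a, intervals_to_granges(ann))
    unique(aln$read_id[S4Vectors::queryHits(hits)])
  }
  ncrna_ids <- union(hit_reads_over(structural),
                     unique(aln$read_id[aln$target == mito_chrom]))
  mirna_ids <- setdiff(hit_reads_over("miRNA"), ncrna_ids)
  lo <- config$pirna_length_range[1]; hi <- config$pirna_length_range[2]
  category <- ifelse(reads$read_id %in% ncrna_ids, "filtered_ncrna",
              ifelse(reads$read_id %in% mirna_ids, "mirna",
              ifelse(reads$length >= lo & reads$length <= hi,
                     "pirna_candidate", "other")))
  data.frame(read_id = reads$read_id, length = reads$length,
             category = category, stringsAsFactors = FALSE)
}

#' MicroRNA normalization factor
#'
#' Scales a library to `mirna_norm_target` sequenced microRNA reads;
#' downstream counts multiply by the returned factor.
#'
#' @param mirna_reads Number of miRNA reads in the library (or a
#'   `small_rna_library`).
#' @param config A [pipeline_config()].
#' @return Positive scalar normalization factor.
#' @export
mirna_norm_factor <- function(mirna_reads, config = pipeline_config()) {
  if (inherits(mirna_reads, "small_rna_library")) {
    mirna_reads <- mirna_reads$mirna_reads
  }
  if (mirna_reads <= 0) {
    stop("library contains no miRNA reads; normalization undefined")
  }
  config$mirna_norm_target / mirna_reads
}

#' Run the small-RNA processing pipeline
#'
#' Trims raw reads, categorizes them from their genome alignments, derives
#' the miRNA normalization factor, and produces the three normalized count
#' tables: antisense length-normalized counts per transposon, locus-unique
#' counts per piRNA cluster, and locus-unique counts per cluster tile. A
#' run report accounts for every read exactly once.
#'
#' @param config A [pipeline_config()].
#' @param fastq Path to raw FASTQ or a named sequence vector.
#' @param scheme An [adapter_scheme()].
#' @param genome_aln Genome alignments of the trimmed reads (all
#'   best-stratum hits; read ids must match the FASTQ).
#' @param annotations Annotation intervals with `feature_type` (must
#'   include miRNA loci).
#' @param te_hits Alignments of the trimmed reads on transposon consensus
#'   sequences.
#' @param te_lengths Named vector of consensus lengths.
#' @param clusters Data frame `(chrom, start, end, name)` of piRNA cluster
#'   intervals.
#' @param tiles Optional `tile_set` for per-tile cluster counts.
#' @param mito_chrom Mitochondrial chromosome name.
#' @param meta Optional [library_meta()].
#' @return List with `library` (a `small_rna_library`), `te_counts`,
#'   `cluster_counts`, `tile_counts` (all normalized by the same miRNA
#'   factor) and `report`.
#' @export
run_smallrna_pipeline <- function(config, fastq, scheme = adapter_scheme(),
                                  genome_aln, annotations, te_hits = NULL,
                                  te_lengths = NULL, clusters = NULL,
                                  tiles = NULL, mito_chrom = "chrM",
                                  meta = NULL) {
  seqs <- if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq))
    read_fastq(fastq) else fastq
  trimmed <- trim_reads(seqs, scheme)
  ok <- trimmed[trimmed$status == "ok", , drop = FALSE]
  cats <- filter_ncrna(ok, genome_aln, annotations,
                       mito_chrom = mito_chrom, config = config)
  n_mirna <- sum(cats$category == "mirna")
  norm <- mirna_norm_factor(n_mirna, config)
  lib <- structure(list(
    reads = merge(ok[, c("read_id", "insert", "barcode")],
                  cats, by = "read_id", sort = FALSE),
    meta = meta, mirna_reads = n_mirna, norm_factor = norm),
    class = "small_rna_library")

  pir_ids <- cats$read_id[cats$category == "pirna_candidate"]
  te_counts <- NULL
  if (!is.null(te_hits) && !is.null(te_lengths)) {
    th <- read_alignments(te_hits)
    th <- th[th$read_id %in% pir_ids, , drop = FALSE]
    assigned <- assign_multimappers(th, seed = config$rng_seed)
    te_counts <- te_antisense_count(assigned, te_lengths, norm, config)
  }
  cluster_counts <- NULL
  tile_counts <- NULL
  genome_aln <- read_alignments(genome_aln)
  pir_aln <- genome_aln[genome_aln$read_id %in% pir_ids, , drop = FALSE]
  if (!is.null(clusters)) {
    cluster_counts <- cluster_unique_count(pir_aln, clusters) * norm
    if (!is.null(tiles)) {
      tile_counts <- tile_unique_count(pir_aln, tiles, clusters) * norm
    }
  }
  report <- data.frame(
    stage = c("raw", "rejected_no_adapter", "rejected_too_short",
              "mirna", "filtered_ncrna", "pirna_candidate", "other"),
    reads = c(length(seqs),
              sum(trimmed$status == "no_adapter"),
              sum(trimmed$status == "too_short"),
              n_mirna,
              sum(cats$category == "filtered_ncrna"),
              sum(cats$category == "pirna_candidate"),
              sum(cats$category == "other")),
    stringsAsFactors = FALSE)
  list(library = lib, te_counts = te_counts,
       cluster_counts = cluster_counts, tile_counts = tile_counts,
       report = report)
}

#' @export
print.small_rna_library <- function(x, ...) {
  cat(sprintf("small_rna_library: %d reads, %d miRNA reads, norm factor %.4g\n",
              nrow(x$reads), x$mirna_reads, x$norm_factor))
  print(table(x$reads$category))
  invisible(x)
}
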