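#' Count genome-unique reads per tile
#'
#' Only reads with a single best-stratum hit (`n_best_hits == 1`) are
#' counted, and each read is assigned to exactly one tile by the position
#' of its midpoint (default) or its 5' end. Reads falling outside every
#' tile still count toward library depth but toward no tile.
#'
#' @param alignments Alignment table or SAM/BAM path.
#' @param tiles A `tile_set`.
#' @param assign `"midpoint"` or `"five_prime"` read-to-tile rule.
#' @return Named integer vector of counts, one entry per tile
#'   (zero-filled), named by `tile_id`.
#' @export
count_unique_reads_per_tile <- function(alignments, tiles,
                                        assign = c("midpoint", "five_prime")) {
  assign <- match.arg(assign)
  aln <- read_alignments(alignments)
  aln <- aln[aln$n_best_hits == 1L, , drop = FALSE]
  counts <- setNames(integer(nrow(tiles)), tiles$tile_id)
  if (!nrow(aln)) return(counts)
  pos <- switch(assign,
    midpoint = (aln$start + aln$end) %/% 2L,
    five_prime = ifelse(aln$strand == "+", aln$start, aln$end - 1L))
  gr_pts <- GenomicRanges::GRanges(aln$target,
                                   IRanges::IRanges(pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_pts, tiles_to_granges(tiles))
  tab <- table(S4Vectors::subjectHits(hits))
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Raw per-tile ChIP enrichment over input
#'
#' Counts are normalized to library depth (reads per `depth_scale` mapped
#' reads), a pseudocount is added to each, and the ratio taken:
#' `(chip * depth_scale/chip_depth + pc) / (input * depth_scale/input_depth
#' + pc)`.
#'
#' @param chip_counts,input_counts Named per-tile counts (same tiles).
#' @param chip_depth,input_depth Total mapped reads per library.
#' @param config A [pipeline_config()].
#' @return Named numeric vector of raw (linear-scale) enrichments.
#' @export
tile_enrichment <- function(chip_counts, input_counts,
                            chip_depth, input_depth,
                            config = pipeline_config()) {
  if (chip_depth <= 0 || input_depth <= 0) {
    stop("library depth must be > 0")
  }
  if (!is.null(names(chip_counts)) && !is.null(names(input_counts))) {
    input_counts <- input_counts[names(chip_counts)]
  }
  pc <- config$pseudocount
  (chip_counts * config$depth_scale / chip_depth + pc) /
    (input_counts * config$depth_scale / input_depth + pc)
}

#' Correct enrichments so the background median is 1
#'
#' The sample-specific correction factor is the reciprocal of the median
#' raw enrichment over the background unit set; after multiplication the
#' median background enrichment equals 1 exactly.
#'
#' @param raw Named numeric vector of raw enrichments.
#' @param background_units Character vector of unit names forming the
#'   background set (defaults to all units).
#' @param unit `"tile"` or `"te_element"` (bookkeeping only).
#' @param libraries Optional list of [library_meta()] records.
#' @return An `enrichment_table`: data frame `(unit, raw, corrected,
#'   log2_corrected)` with attributes `correction_factor`,
#'   `background_units`, `unit_type`.
#' @export
background_correction <- function(raw, background_units = names(raw),
                                  unit = c("tile", "te_element"),
                                  libraries = NULL) {
  unit <- match.arg(unit)
  if (!length(background_units)) stop("background_units must be non-empty")
  bg <- raw[background_units]
  if (anyNA(bg)) stop("background unit(s) missing from enrichment vector")
  med <- median(bg)
  if (med == 0) stop("background median enrichment is 0; cannot correct")
  fac <- 1 / med
  corrected <- raw * fac
  structure(
    data.frame(unit = names(raw), raw = unname(raw),
               corrected = unname(corrected),
               log2_corrected = log2(unname(corrected)),
               stringsAsFactors = FALSE),
    class = c("enrichment_table", "data.frame"),
    correction_factor = fac,
    background_units = background_units,
    unit_type = unit,
    libraries = libraries)
}

#' Correction factor applied to an enrichment table
#' @param x An `enrichment_table`.
#' @return The multiplicative correction factor.
#' @export
correction_factor <- function(x) attr(x, "correction_factor")

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table (%s): %d units, correction factor %.4g\n",
              attr(x, "unit_type"), nrow(x), attr(x, "correction_factor")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Assign each multimapping read to a single hit
#'
#' The unique minimal-mismatch hit wins ("best mapping"); ties are broken
#' uniformly at random ("randomly distributed") with a seeded generator.
#' Reads are processed in lexicographic read-id order so the assignment is
#' reproducible regardless of input record order.
#'
#' @param alignments Alignment table (possibly multiple rows per read).
#' @param seed Integer seed for the tie-breaking generator.
#' @return Alignment table with exactly one row per read.
#' @export
assign_multimappers <- function(alignments, seed = 1L) {
  aln <- read_alignments(alignments)
  if (!nrow(aln)) return(aln)
  ord <- order(aln$read_id, aln$target, aln$start)
  aln <- aln[ord, , drop = FALSE]
  grp <- match(aln$read_id, unique(aln$read_id))
  minmm <- tapply(aln$mismatches, grp, min)[grp]
  best <- aln$mismatches == minmm
  keep <- integer(max(grp))
  rows_best <- split(which(best), grp[best])
  set.seed(seed)
  for (g in seq_along(rows_best)) {
    rows <- rows_best[[g]]
    keep[g] <- if (length(rows) == 1L) rows else rows[sample.int(length(rows), 1L)]
  }
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position mean coverage of each reference element
#'
#' Mean over all nucleotide positions of an element of the per-base read
#' coverage, i.e. total aligned bases divided by element length.
#'
#' @param aln Alignment table (one row per read after assignment).
#' @param element_lengths Named vector of element lengths.
#' @return Named numeric vector of mean coverages (one per element,
#'   zero-filled).
#' @export
mean_element_coverage <- function(aln, element_lengths) {
  if (any(element_lengths <= 0)) {
    stop("element of length 0: ",
         paste(names(element_lengths)[element_lengths <= 0], collapse = ", "))
  }
  cov <- setNames(numeric(length(element_lengths)), names(element_lengths))
  if (!nrow(aln)) return(cov)
  clip_start <- pmax(aln$start, 0L)
  clip_end <- pmin(aln$end, element_lengths[aln$target])
  bases <- tapply(pmax(clip_end - clip_start, 0L), aln$target, sum)
  cov[names(bases)] <- as.numeric(bases) / element_lengths[names(bases)]
  cov
}

#' ChIP enrichment on transposon consensus sequences
#'
#' Reads longer than 23 nt (configurable) are kept; multimappers are
#' assigned to the best hit with random tie-breaking; per element the mean
#' over consensus positions of depth-normalized coverage is computed for
#' ChIP and input; enrichment is `(chip_mean + pc) / (input_mean + pc)`,
#' scaled by the sample-specific correction factor determined from
#' background genomic tiles.
#'
#' @param chip_hits,input_hits Alignment tables of all best-stratum hits on
#'   the consensus set.
#' @param te_lengths Named vector of consensus lengths.
#' @param correction_factor Sample correction factor from the same
#'   library's tile-level background (default 1).
#' @param config A [pipeline_config()].
#' @param chip_depth,input_depth Library depths; default: number of
#'   distinct reads in each hit table.
#' @param seed Seed for multimapper tie-breaking.
#' @return An `enrichment_table` over elements.
#' @export
te_consensus_enrichment <- function(chip_hits, input_hits, te_lengths,
                                    correction_factor = 1,
                                    config = pipeline_config(),
                                    chip_depth = NULL, input_depth = NULL,
                                    seed = config$rng_seed) {
  one_side <- function(hits, depth, seed) {
    aln <- read_alignments(hits)
    aln <- aln[aln$read_length >= config$te_min_read_length, , drop = FALSE]
    if (is.null(depth)) depth <- length(unique(aln$read_id))
    assigned <- assign_multimappers(aln, seed = seed)
    cov <- mean_element_coverage(assigned, te_lengths)
    if (depth > 0) cov <- cov * config$depth_scale / depth
    cov
  }
  chip_mean <- one_side(chip_hits, chip_depth, seed)
  input_mean <- one_side(input_hits, input_depth, seed + 1L)
  pc <- config$pseudocount
  raw <- (chip_mean + pc) / (input_mean + pc)
  out <- structure(
    data.frame(unit = names(raw),
               chip_mean = unname(chip_mean),
               input_mean = unname(input_mean),
               raw = unname(raw),
               corrected = unname(raw * correction_factor),
               log2_corrected = log2(unname(raw * correction_factor)),
               stringsAsFactors = FALSE),
    class = c("enrichment_table", "data.frame"),
    correction_factor = correction_factor,
    background_units = character(),
    unit_type = "te_element")
  out
}

#' Run the tile-level ChIP enrichment pipeline
#'
#' Counts genome-unique reads on the curated tiles for ChIP and input,
#' computes raw enrichments with depth normalization and pseudocount, and
#' applies the background-median correction. Background units default to
#' all curated tiles.
#'
#' @param config A [pipeline_config()].
#' @param chip,input Alignment tables or SAM/BAM paths.
#' @param tiles A curated `tile_set`.
#' @param background_units Optional explicit background tile ids.
#' @param libraries Optional list with `chip` and `input` [library_meta()].
#' @return An `enrichment_table` over curated tiles.
#' @export
run_chip_pipeline <- function(config, chip, input, tiles,
                              background_units = NULL, libraries = NULL) {
  chip <- read_alignments(chip)
  input <- read_alignments(input)
  if (!nrow(chip) || !nrow(input)) stop("no mapped reads")
  for (aln in list(chip, input)) {
    bad <- setdiff(unique(aln$target), unique(tiles$chrom))
    if (length(bad)) {
      stop("alignment chromosome(s) absent from tile set: ",
           paste(bad, collapse = ", "))
    }
  }
  chip_depth <- length(unique(chip$read_id))
  input_depth <- length(unique(input$read_id))
  chip_counts <- count_unique_reads_per_tile(chip, tiles)
  input_counts <- count_unique_reads_per_tile(input, tiles)
  curated <- tiles$tile_id[tiles$curated]
  raw <- tile_enrichment(chip_counts[curated], input_counts[curated],
                         chip_depth, input_depth, config)
  if (is.null(background_units)) background_units <- curated
  background_correction(raw, background_units, unit = "tile",
                        libraries = libraries)
}

#' Average replicate enrichment tables
#'
#' Per unit, the arithmetic mean of the log2 corrected enrichments across
#' replicates, returned on both scales.
#'
#' @param tables List of >= 2 `enrichment_table`s over the same units.
#' @return Data frame `(unit, log2_corrected, corrected)`.
#' @export
average_replicates <- function(tables) {
  stopifnot(length(tables) >= 2L)
  units <- tables[[1]]$unit
  for (t in tables[-1]) {
    if (!identical(t$unit, units)) stop("replicates cover different units")
  }
  logs <- vapply(tables, function(t) t$log2_corrected, numeric(length(units)))
  m <- rowMeans(logs)
  data.frame(unit = units, log2_corrected = m, corrected = 2^m,
             stringsAsFactors = FALSE)
}

#' Write an enrichment table as TSV
#' @param x An `enrichment_table`.
#' @param path Output path.
#' @export
write_enrichment <- function(x, path) {
  df <- as.data.frame(x)
  attr(df, "correction_factor") <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# correction_factor\t%.10g", correction_factor(x)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
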