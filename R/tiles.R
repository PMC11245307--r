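#' @import methods
#' @importFrom stats median rbinom runif setNames complete.cases
#' @importFrom utils read.table write.table head tail
NULL

## Internal convention: all interval coordinates are 0-based, half-open.
## GRanges (1-based, closed) is used only transiently for overlap work.

tiles_to_granges <- function(tiles) {
  GenomicRanges::GRanges(tiles$chrom,
                         IRanges::IRanges(start = tiles$start + 1L,
                                          end = tiles$end))
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1L,
              end = GenomicRanges::end(gr),
              stringsAsFactors = FALSE)
}

new_tile_set <- function(df, genome_id, tile_size) {
  rownames(df) <- NULL
  structure(df, class = c("tile_set", "data.frame"),
            genome_id = genome_id, tile_size = as.integer(tile_size))
}

#' Generate non-overlapping genomic tiles
#'
#' Partitions each chromosome into consecutive fixed-width windows; a short
#' terminal window is retained with its true length.
#'
#' @param chrom_sizes Named numeric vector (chromosome name to length in
#'   bases) or a two-column data frame `(chrom, length)`.
#' @param tile_size Tile width in bases.
#' @param genome_id Optional genome label stored on the result.
#' @return A `tile_set`: a data frame with columns `chrom`, `start`, `end`
#'   (0-based, half-open), `tile_id`, `mappable_fraction`, `curated`,
#'   `excluded_by`, `cluster_label`.
#' @examples
#' make_tiles(c(chr2L = 3500), tile_size = 1000)
#' @export
make_tiles <- function(chrom_sizes, tile_size = 1000L, genome_id = "genome") {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]),
                            as.character(chrom_sizes[[1]]))
  }
  if (any(chrom_sizes < 0)) stop("chromosome lengths must be >= 0")
  tile_size <- as.integer(tile_size)
  stopifnot(tile_size >= 1L)
  pieces <- lapply(names(chrom_sizes), function(chr) {
    len <- as.integer(chrom_sizes[[chr]])
    if (len == 0L) return(NULL)
    starts <- seq.int(0L, len - 1L, by = tile_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + tile_size, len),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  if (is.null(df)) {
    df <- data.frame(chrom = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
  }
  df$tile_id <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  df$mappable_fraction <- rep(NA_real_, nrow(df))
  df$curated <- rep(TRUE, nrow(df))
  df$excluded_by <- rep("", nrow(df))
  df$cluster_label <- rep(NA_character_, nrow(df))
  new_tile_set(df, genome_id, tile_size)
}

#' Compute per-tile mappability from blocks of continuous mappability
#'
#' @param tiles A `tile_set`.
#' @param mappable_blocks Data frame `(chrom, start, end)` (0-based,
#'   half-open) or a `GRanges`; overlapping blocks are merged on ingest.
#' @return The `tile_set` with `mappable_fraction` filled in as covered
#'   bases divided by tile length.
#' @export
compute_mappability <- function(tiles, mappable_blocks) {
  gr_tiles <- tiles_to_granges(tiles)
  gr_blocks <- if (methods::is(mappable_blocks, "GRanges")) mappable_blocks
               else intervals_to_granges(mappable_blocks)
  unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(gr_blocks))),
                     unique(tiles$chrom))
  if (length(unknown)) {
    warning("mappability blocks on unknown chromosome(s) ignored: ",
            paste(unknown, collapse = ", "))
    gr_blocks <- gr_blocks[!(as.character(GenomicRanges::seqnames(gr_blocks))
                             %in% unknown)]
  }
  GenomeInfoDb::seqlevels(gr_blocks, pruning.mode = "coarse") <-
    unique(tiles$chrom)
  gr_blocks <- GenomicRanges::reduce(gr_blocks, ignore.strand = TRUE)
  cov <- rep(0L, length(gr_tiles))
  hits <- GenomicRanges::findOverlaps(gr_tiles, gr_blocks)
  if (length(hits)) {
    ov <- IRanges::pintersect(gr_tiles[S4Vectors::queryHits(hits)],
                              gr_blocks[S4Vectors::subjectHits(hits)])
    w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    cov[as.integer(names(w))] <- as.integer(w)
  }
  tiles$mappable_fraction <- cov / (tiles$end - tiles$start)
  tiles
}

#' Annotate tiles with piRNA cluster membership
#'
#' @param tiles A `tile_set`.
#' @param clusters Data frame `(chrom, start, end, name)` (0-based,
#'   half-open) of cluster intervals.
#' @param min_overlap Minimum overlap in bases for a tile to receive the
#'   cluster label (default 1).
#' @return The `tile_set` with `cluster_label` filled where a tile overlaps
#'   a cluster interval.
#' @export
annotate_clusters <- function(tiles, clusters, min_overlap = 1L) {
  gr_tiles <- tiles_to_granges(tiles)
  gr_cl <- intervals_to_granges(clusters)
  hits <- GenomicRanges::findOverlaps(gr_tiles, gr_cl,
                                      minoverlap = min_overlap)
  tiles$cluster_label <- NA_character_
  if (length(hits)) {
    tiles$cluster_label[S4Vectors::queryHits(hits)] <-
      as.character(clusters$name[S4Vectors::subjectHits(hits)])
  }
  tiles
}

#' Apply the three tile-curation filters
#'
#' Excludes tiles with low mappability, tiles whose representative input
#' count deviates more than `input_deviation_fold` from the across-tile
#' median (two-sided, strict inequality), and, when knockout ChIP
#' enrichments are supplied, tiles with strong residual signal in the
#' knockout. Filters are applied independently and every triggered filter
#' is recorded in `excluded_by`.
#'
#' @param tiles A `tile_set` with `mappable_fraction` computed.
#' @param representative_input_counts Named numeric vector (tile_id to
#'   count) or vector aligned with the tiles.
#' @param ko_chip_enrichment Optional named numeric vector of log2
#'   enrichments in knockout ChIP libraries.
#' @param config A [pipeline_config()].
#' @return The curated `tile_set`; `curated` is `TRUE` iff `excluded_by` is
#'   empty.
#' @export
curate_tiles <- function(tiles, representative_input_counts,
                         ko_chip_enrichment = NULL,
                         config = pipeline_config()) {
  counts <- align_tile_values(tiles, representative_input_counts,
                              "representative_input_counts")
  if (!length(counts) || all(is.na(counts))) {
    stop("empty input count table: cannot apply the input-deviation filter")
  }
  excl <- vector("list", nrow(tiles))
  low_map <- !is.na(tiles$mappable_fraction) &
    tiles$mappable_fraction < config$mappability_min
  med <- median(counts, na.rm = TRUE)
  dev <- counts > config$input_deviation_fold * med |
    counts < med / config$input_deviation_fold
  dev[is.na(dev)] <- FALSE
  flags <- cbind(mappability = low_map, input_deviation = dev)
  if (!is.null(ko_chip_enrichment)) {
    ko <- align_tile_values(tiles, ko_chip_enrichment, "ko_chip_enrichment")
    res <- !is.na(ko) & ko > config$ko_residual_log2_max
    flags <- cbind(flags, ko_residual = res)
  }
  tiles$excluded_by <- apply(flags, 1L, function(f)
    paste(colnames(flags)[f], collapse = ","))
  tiles$curated <- tiles$excluded_by == ""
  tiles
}

## Accept per-tile values as either a tiles-aligned vector or a named
## vector keyed by tile_id; return a vector aligned with `tiles`.
align_tile_values <- function(tiles, values, what) {
  if (is.null(names(values))) {
    if (length(values) != nrow(tiles)) {
      stop(what, " must be named by tile_id or have one value per tile")
    }
    return(as.numeric(values))
  }
  as.numeric(values[tiles$tile_id])
}

#' Read a two-column chromosome sizes file
#'
#' @param path Tab-separated file with columns name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df$length), df$chrom)
}

#' Read a BED file into a 0-based half-open interval table
#'
#' @param path Path to a BED file (3+ columns).
#' @return Data frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_intervals(gr)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands != "*")) out$strand <- strands
  out
}

#' Write intervals as BED
#'
#' @param df Data frame with `chrom`, `start`, `end` (0-based, half-open)
#'   and optional `name`, `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- data.frame(chrom = df$chrom, start = df$start, end = df$end)
  cols$name <- if (!is.null(df$name)) df$name else "."
  cols$score <- if (!is.null(df$score)) df$score else 0
  cols$strand <- if (!is.null(df$strand)) df$strand else "."
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tile set as a BED-plus-columns TSV
#'
#' @param tiles A `tile_set`.
#' @param path Output path.
#' @export
write_tiles <- function(tiles, path) {
  write.table(as.data.frame(tiles), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a tile set written by [write_tiles()]
#'
#' @param path Path to the TSV.
#' @param genome_id Genome label to attach.
#' @return A `tile_set`.
#' @export
read_tiles <- function(path, genome_id = "genome") {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  df$excluded_by[is.na(df$excluded_by)] <- ""
  tile_size <- max(df$end - df$start)
  new_tile_set(df, genome_id, tile_size)
}
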