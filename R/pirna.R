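#' Antisense, length-normalized piRNA counts per transposon
#'
#' Only antisense reads are counted; counts are scaled by the library's
#' miRNA normalization factor and by transposon length (per kilobase).
#'
#' @param assigned_hits Alignment table with one row per read (after
#'   [assign_multimappers()]); `strand` is relative to the consensus, so
#'   `-` is antisense.
#' @param te_lengths Named vector of consensus lengths (> 0).
#' @param norm_factor miRNA normalization factor.
#' @param config A [pipeline_config()].
#' @return Named numeric vector: normalized antisense reads per kb per
#'   element (zero-filled over `te_lengths`).
#' @export
te_antisense_count <- function(assigned_hits, te_lengths, norm_factor = 1,
                               config = pipeline_config()) {
  if (any(te_lengths <= 0)) {
    stop("transposon of length 0: ",
         paste(names(te_lengths)[te_lengths <= 0], collapse = ", "))
  }
  aln <- read_alignments(assigned_hits)
  anti <- aln[aln$strand == "-", , drop = FALSE]
  counts <- setNames(numeric(length(te_lengths)), names(te_lengths))
  if (nrow(anti)) {
    tab <- table(anti$target)
    tab <- tab[names(tab) %in% names(counts)]
    counts[names(tab)] <- as.numeric(tab)
  }
  counts * norm_factor * 1000 / te_lengths
}

## 0-based 5' end coordinate of each hit (leftmost base for +, rightmost
## for -).
five_prime_pos <- function(aln) {
  ifelse(aln$strand == "+", aln$start, aln$end - 1L)
}

## Map each hit's 5' end to a cluster name (NA when outside all clusters).
hit_cluster <- function(aln, clusters) {
  pos <- five_prime_pos(aln)
  gr_pts <- GenomicRanges::GRanges(aln$target,
                                   IRanges::IRanges(pos + 1L, width = 1L))
  gr_cl <- intervals_to_granges(clusters)
  hits <- GenomicRanges::findOverlaps(gr_pts, gr_cl, select = "first")
  ifelse(is.na(hits), NA_character_, as.character(clusters$name[hits]))
}

#' Locus-unique piRNA counts per cluster
#'
#' A read contributes one count to cluster C if and only if the 5' end of
#' every one of its genome hits lies within C's intervals — reads touching
#' a second locus or any position outside all clusters are discarded, and
#' reads mapping multiple times within one cluster are counted once.
#'
#' @param genome_aln Alignment table carrying the complete best-stratum
#'   hit list of every read.
#' @param clusters Data frame `(chrom, start, end, name)`; intervals of a
#'   cluster may be split across rows.
#' @return Named numeric vector of counts per cluster name (zero-filled).
#' @export
cluster_unique_count <- function(genome_aln, clusters) {
  aln <- read_alignments(genome_aln)
  counts <- setNames(numeric(length(unique(clusters$name))),
                     unique(clusters$name))
  if (!nrow(aln)) return(counts)
  cl <- hit_cluster(aln, clusters)
  per_read <- split(cl, aln$read_id)
  assigned <- vapply(per_read, function(x) {
    u <- unique(x)
    if (length(u) == 1L && !is.na(u)) u else NA_character_
  }, character(1))
  tab <- table(assigned[!is.na(assigned)])
  counts[names(tab)] <- as.numeric(tab)
  counts
}

#' Locus-unique piRNA counts per cluster tile
#'
#' Applies the cluster locus-unique rule ([cluster_unique_count()]), then
#' counts each qualifying read once on the tile containing the 5' end of
#' its leftmost hit. Tiles outside clusters receive no counts.
#'
#' @param genome_aln Complete hit lists per read.
#' @param tiles A `tile_set`.
#' @param clusters Cluster interval table.
#' @return Named numeric vector of counts over cluster tiles.
#' @export
tile_unique_count <- function(genome_aln, tiles, clusters) {
  aln <- read_alignments(genome_aln)
  gr_cl <- intervals_to_granges(clusters)
  in_cluster <- IRanges::overlapsAny(tiles_to_granges(tiles), gr_cl)
  counts <- setNames(numeric(sum(in_cluster)), tiles$tile_id[in_cluster])
  if (!nrow(aln)) return(counts)
  cl <- hit_cluster(aln, clusters)
  keep_read <- vapply(split(cl, aln$read_id), function(x) {
    u <- unique(x); length(u) == 1L && !is.na(u)
  }, logical(1))
  aln <- aln[keep_read[aln$read_id], , drop = FALSE]
  if (!nrow(aln)) return(counts)
  aln <- aln[order(aln$read_id, aln$target, aln$start), , drop = FALSE]
  first <- aln[!duplicated(aln$read_id), , drop = FALSE]
  pos <- five_prime_pos(first)
  gr_pts <- GenomicRanges::GRanges(first$target,
                                   IRanges::IRanges(pos + 1L, width = 1L))
  idx <- GenomicRanges::findOverlaps(gr_pts, tiles_to_granges(tiles),
                                     select = "first")
  tab <- table(tiles$tile_id[idx[!is.na(idx)]])
  tab <- tab[names(tab) %in% names(counts)]
  counts[names(tab)] <- as.numeric(tab)
  counts
}

#' Per-tile piRNA log2 fold changes across genotypes
#'
#' Tiles with a read count of zero in any analyzed genotype are excluded;
#' for the rest, `log2(count_genotype / count_control)` is reported per
#' non-control genotype.
#'
#' @param counts Named list of per-tile normalized count vectors, one per
#'   genotype, all over the same tiles.
#' @param control Name of the control genotype in `counts`.
#' @param cluster_tiles Optional character vector restricting the analysis
#'   to these tile ids.
#' @return List with `log2fc` (data frame `tile_id` x genotype columns)
#'   and `excluded` (data frame `tile_id`, `reason`).
#' @export
tile_pirna_log2fc <- function(counts, control, cluster_tiles = NULL) {
  if (!control %in% names(counts)) {
    stop("control genotype '", control, "' absent from count tables")
  }
  ids <- names(counts[[control]])
  if (!is.null(cluster_tiles)) ids <- intersect(ids, cluster_tiles)
  mat <- vapply(counts, function(x) x[ids], numeric(length(ids)))
  rownames(mat) <- ids
  zero <- rowSums(mat == 0) > 0
  excluded <- data.frame(tile_id = ids[zero],
                         reason = "zero count in >=1 genotype",
                         stringsAsFactors = FALSE)
  kept <- mat[!zero, , drop = FALSE]
  others <- setdiff(colnames(kept), control)
  lfc <- as.data.frame(log2(kept[, others, drop = FALSE] / kept[, control]))
  lfc <- cbind(data.frame(tile_id = rownames(kept),
                          stringsAsFactors = FALSE), lfc)
  rownames(lfc) <- NULL
  list(log2fc = lfc, excluded = excluded)
}

#' Classify transposons as Rhino-dependent or -independent
#'
#' An element is called dependent when its normalized antisense piRNA count
#' in the test condition is reduced at least `dependence_fold`-fold
#' relative to control (boundary inclusive: an exactly twofold reduction is
#' dependent). Elements with a control count of zero are unclassifiable.
#'
#' @param control_counts,test_counts Named normalized count vectors over
#'   the same elements (same tissue).
#' @param config A [pipeline_config()].
#' @return Data frame `(element, control_value, test_value, ratio, call)`
#'   with `call` in `dependent`, `independent`, `unclassifiable`.
#' @export
classify_dependence <- function(control_counts, test_counts,
                                config = pipeline_config()) {
  elements <- names(control_counts)
  test_counts <- test_counts[elements]
  ratio <- ifelse(control_counts > 0, test_counts / control_counts, NA_real_)
  call <- ifelse(control_counts == 0, "unclassifiable",
          ifelse(test_counts <= control_counts / config$dependence_fold,
                 "dependent", "independent"))
  data.frame(element = elements,
             control_value = unname(control_counts),
             test_value = unname(test_counts),
             ratio = unname(ratio), call = unname(call),
             stringsAsFactors = FALSE, row.names = NULL)
}
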