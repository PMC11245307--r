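## Synthetic-data generators. Every generator is a pure function of its
## arguments plus an integer seed, and records enough ground truth to
## recompute the expected output of every downstream stage analytically.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy genome with repeats, clusters and annotations
#'
#' Builds random chromosomes, a set of transposon consensus sequences with
#' several copies embedded inside piRNA clusters (so that reads from them
#' are legitimate multimappers), miRNA and structural ncRNA loci, a small
#' mitochondrial chromosome, and planted low-mappability blocks. The
#' mappability track is the complement of the planted blocks.
#'
#' Copies of each transposon are spread across different clusters, so
#' transposon-derived reads are never locus-unique; locus-unique cluster
#' reads come from non-repetitive cluster sequence.
#'
#' @param chrom_lengths Named vector of chromosome lengths (default two
#'   100-kb chromosomes).
#' @param n_clusters Number of piRNA clusters (default 2; length 10 kb).
#' @param n_tes Number of transposon consensi (default 3; length 2 kb).
#' @param copies_per_te Embedded copies per consensus (default 2, one per
#'   cluster where possible).
#' @param n_mirna,n_ncrna Number of miRNA and structural ncRNA loci.
#' @param n_lowmap Number of planted low-mappability blocks (3 kb each).
#' @param seed Integer seed.
#' @return A `sim_genome` list: `genome`, `chrom_sizes`, `te_seqs`,
#'   `te_lengths`, `clusters`, `mirna`, `ncrna`, `annotations`,
#'   `mappable`, `te_copies`, `mito_chrom`, `seed`.
#' @export
sim_genome <- function(chrom_lengths = c(chr2L = 1e5, chr3L = 1e5),
                       n_clusters = 2L, n_tes = 3L, copies_per_te = 2L,
                       n_mirna = 4L, n_ncrna = 4L, n_lowmap = 2L,
                       seed = 1L) {
  set.seed(seed)
  cluster_len <- 10000L; te_len <- 2000L; lowmap_len <- 3000L
  need <- n_clusters * cluster_len + n_lowmap * lowmap_len +
    (n_mirna + n_ncrna) * 200L
  if (need > sum(chrom_lengths)) {
    stop("infeasible layout: requested features exceed genome size")
  }
  genome <- lapply(chrom_lengths, function(n) random_dna(n))
  names(genome) <- names(chrom_lengths)
  chroms <- names(chrom_lengths)

  ## lay out non-overlapping feature slots left to right, alternating
  ## chromosomes, with 2-kb spacers
  slots <- list(); cursor <- setNames(rep(1000L, length(chroms)), chroms)
  place <- function(len, kind) {
    chr <- chroms[which.min(cursor / chrom_lengths[chroms])]
    start <- cursor[[chr]]
    if (start + len > chrom_lengths[[chr]] - 1000L) {
      stop("infeasible layout: feature '", kind, "' exceeds chromosome ",
           chr)
    }
    cursor[[chr]] <<- start + len + 2000L
    data.frame(chrom = chr, start = start, end = start + len,
               stringsAsFactors = FALSE)
  }
  clusters <- do.call(rbind, lapply(seq_len(n_clusters), function(i)
    cbind(place(cluster_len, "cluster"),
          name = sprintf("cluster%02d", i))))
  lowmap <- if (n_lowmap > 0)
    do.call(rbind, lapply(seq_len(n_lowmap), function(i)
      place(lowmap_len, "lowmap"))) else NULL
  mirna <- if (n_mirna > 0)
    do.call(rbind, lapply(seq_len(n_mirna), function(i)
      cbind(place(100L, "miRNA"), feature_type = "miRNA",
            name = sprintf("mir-%d", i)))) else NULL
  nc_types <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA"),
                  length.out = n_ncrna)
  ncrna <- if (n_ncrna > 0)
    do.call(rbind, lapply(seq_len(n_ncrna), function(i)
      cbind(place(150L, nc_types[i]), feature_type = nc_types[i],
            name = sprintf("nc-%d", i)))) else NULL

  ## transposon consensi, embedded inside clusters (spread across
  ## clusters so copies of one element sit in different loci)
  te_names <- sprintf("TE_%d", seq_len(n_tes))
  te_seqs <- setNames(vapply(te_names, function(x) random_dna(te_len),
                             character(1)), te_names)
  te_copies <- NULL
  if (n_tes > 0 && copies_per_te > 0 && n_clusters > 0) {
    copy_list <- list()
    for (i in seq_len(n_tes)) {
      for (k in seq_len(copies_per_te)) {
        cl <- clusters[((i + k - 2L) %% n_clusters) + 1L, ]
        offset <- 500L + (i - 1L) * (te_len + 500L)
        start <- cl$start + offset
        if (start + te_len > cl$end) {
          stop("infeasible layout: transposon copies exceed cluster size")
        }
        copy_list[[length(copy_list) + 1L]] <- data.frame(
          chrom = cl$chrom, start = start, end = start + te_len,
          te = te_names[i], cluster = cl$name, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
    te_copies <- do.call(rbind, copy_list)
    for (j in seq_len(nrow(te_copies))) {
      cp <- te_copies[j, ]
      substr(genome[[cp$chrom]], cp$start + 1L, cp$end) <- te_seqs[[cp$te]]
    }
  }

  ## mitochondrial chromosome
  mito <- "chrM"
  genome[[mito]] <- random_dna(5000L)
  chrom_sizes <- c(chrom_lengths, setNames(5000L, mito))

  mappable <- do.call(rbind, lapply(chroms, function(chr) {
    blocks <- data.frame(chrom = chr, start = 0L,
                         end = as.integer(chrom_lengths[[chr]]),
                         stringsAsFactors = FALSE)
    if (!is.null(lowmap)) {
      lm <- lowmap[lowmap$chrom == chr, , drop = FALSE]
      if (nrow(lm)) {
        gr <- GenomicRanges::setdiff(intervals_to_granges(blocks),
                                     intervals_to_granges(lm))
        blocks <- granges_to_intervals(gr)
      }
    }
    blocks
  }))
  annotations <- rbind(
    if (!is.null(ncrna)) ncrna[, c("chrom", "start", "end",
                                   "feature_type")] else NULL,
    if (!is.null(mirna)) mirna[, c("chrom", "start", "end",
                                   "feature_type")] else NULL)
  structure(list(genome = genome, chrom_sizes = chrom_sizes,
                 te_seqs = te_seqs,
                 te_lengths = setNames(rep(te_len, n_tes), te_names),
                 clusters = clusters, mirna = mirna, ncrna = ncrna,
                 annotations = annotations, mappable = mappable,
                 lowmap = lowmap, te_copies = te_copies,
                 mito_chrom = mito, seed = seed),
            class = "sim_genome")
}

#' Write a simulated genome to standard files
#'
#' Emits genome FASTA, chrom.sizes TSV, transposon consensus FASTA, and
#' BED files for clusters, annotations and mappability blocks.
#'
#' @param sim A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths.
#' @export
write_sim_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             sizes = file.path(dir, "genome.chrom.sizes"),
             te = file.path(dir, "te_consensus.fa"),
             clusters = file.path(dir, "clusters.bed"),
             annotations = file.path(dir, "annotations.bed"),
             mappable = file.path(dir, "mappable.bed"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(sim$genome)), paths["genome"])
  write.table(data.frame(names(sim$chrom_sizes),
                         as.integer(sim$chrom_sizes)),
              paths["sizes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$te_seqs),
                              paths["te"])
  write_bed(sim$clusters, paths["clusters"])
  ann <- sim$annotations
  ann$name <- ann$feature_type
  write_bed(ann, paths["annotations"])
  write_bed(sim$mappable, paths["mappable"])
  paths
}

#' Simulate ChIP and input libraries over a simulated genome
#'
#' Input read midpoints are uniform over the mappable space; ChIP reads
#' are sampled per tile proportional to the tile's enrichment multiplier
#' times its mappable length. Multipliers default to background 1 with a
#' few planted enriched domains at 2x, 4x and 8x. All reads are
#' genome-unique with zero mismatches.
#'
#' @param sim A [sim_genome()].
#' @param n_reads Reads per library.
#' @param multipliers Enrichment levels of the planted domains.
#' @param tiles_per_domain Tiles planted per enrichment level.
#' @param read_length Read length in bases.
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return A `sim_chip` list: `chip`, `input` (alignment tables),
#'   `tile_multiplier` (named truth vector over all tiles), `tiles`,
#'   `n_reads`, `seed`.
#' @export
sim_chip <- function(sim, n_reads = 1e5, multipliers = c(2, 4, 8),
                     tiles_per_domain = 5L, read_length = 50L,
                     config = pipeline_config(), seed = 1L) {
  set.seed(seed)
  tiles <- make_tiles(sim$chrom_sizes[names(sim$chrom_sizes) !=
                                        sim$mito_chrom],
                      config$tile_size)
  tiles <- compute_mappability(tiles, sim$mappable)
  if (n_reads < nrow(tiles)) {
    warning("n_reads < number of tiles: sparse regime")
  }
  ## mappable bases of each tile define its sampling space
  half <- read_length %/% 2L
  usable <- tiles$mappable_fraction * (tiles$end - tiles$start)
  mult <- setNames(rep(1, nrow(tiles)), tiles$tile_id)
  candidates <- which(usable >= 0.9 * config$tile_size &
                        is.na(tiles$cluster_label))
  need <- length(multipliers) * tiles_per_domain
  if (length(candidates) < need) stop("not enough tiles to plant domains")
  planted <- sample(candidates, need)
  mult[planted] <- rep(multipliers, each = tiles_per_domain)

  sample_reads <- function(weights, prefix) {
    idx <- sample.int(nrow(tiles), n_reads, replace = TRUE,
                      prob = weights)
    lo <- tiles$start[idx] + half
    hi <- pmax(tiles$end[idx] - half - 1L, lo)
    mid <- lo + floor(runif(n_reads) * (hi - lo + 1L))
    data.frame(read_id = sprintf("%s_%07d", prefix, seq_len(n_reads)),
               target = tiles$chrom[idx],
               start = mid - half, end = mid - half + read_length,
               strand = sample(c("+", "-"), n_reads, replace = TRUE),
               mismatches = 0L, n_best_hits = 1L,
               read_length = read_length, stringsAsFactors = FALSE)
  }
  input <- sample_reads(usable, "inp")
  chip <- sample_reads(usable * mult, "chip")
  structure(list(chip = chip, input = input, tile_multiplier = mult,
                 tiles = tiles, n_reads = n_reads, seed = seed),
            class = "sim_chip")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a raw small-RNA library with full adapter architecture
#'
#' Emits raw reads (insert + 6 random nt + 5 nt barcode + constant linker,
#' with 4 random nt at the 5' end), companion exact-match genome and
#' transposon-consensus alignment tables for the trimmed inserts, and an
#' analytically computed expected-count table.
#'
#' Transposon piRNAs are drawn from the consensus sequences and hit every
#' embedded genome copy (multimappers across clusters, hence never
#' locus-unique); cluster-unique piRNAs come from non-repetitive cluster
#' sequence; miRNA reads are 22 nt from miRNA loci; structural ncRNA reads
#' are planted for the filter.
#'
#' @param sim A [sim_genome()].
#' @param composition List with `n_mirna` (required, > 0),
#'   `te_antisense` / `te_sense` (named per-element read counts),
#'   `cluster_unique` (named per-cluster read counts), `n_ncrna`.
#' @param scheme An [adapter_scheme()].
#' @param barcode Library barcode (nchar = `scheme$barcode_len`).
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return A `sim_srna` list: `fastq` (named raw sequences), `genome_aln`,
#'   `te_aln` (alignment tables of the trimmed inserts), `expected` (norm
#'   factor, category counts, normalized per-element antisense counts,
#'   per-cluster counts), `seed`.
#' @export
sim_srna <- function(sim, composition = list(), scheme = adapter_scheme(),
                     barcode = "CGTAC", config = pipeline_config(),
                     seed = 1L) {
  set.seed(seed)
  comp <- utils::modifyList(list(n_mirna = 1000L, n_ncrna = 200L,
                                 te_antisense = NULL, te_sense = NULL,
                                 cluster_unique = NULL), composition)
  if (is.null(comp$n_mirna) || comp$n_mirna <= 0) {
    stop("composition must plant > 0 miRNA reads (normalization undefined)")
  }
  te_names <- names(sim$te_lengths)
  if (is.null(comp$te_antisense)) {
    comp$te_antisense <- setNames(rep(300L, length(te_names)), te_names)
  }
  if (is.null(comp$te_sense)) {
    comp$te_sense <- setNames(rep(100L, length(te_names)), te_names)
  }
  if (is.null(comp$cluster_unique)) {
    comp$cluster_unique <- setNames(rep(200L, nrow(sim$clusters)),
                                    sim$clusters$name)
  }

  reads <- list(); genome_hits <- list(); te_hits <- list()
  add_read <- function(id, insert, ghits, thits = NULL) {
    reads[[id]] <<- insert
    if (!is.null(ghits)) genome_hits[[id]] <<- ghits
    if (!is.null(thits)) te_hits[[id]] <<- thits
  }
  sub_seq <- function(chr, start, len) {
    substr(sim$genome[[chr]], start + 1L, start + len)
  }

  ## miRNA reads: 22 nt from a miRNA locus, plus strand, unique
  for (i in seq_len(comp$n_mirna)) {
    loc <- sim$mirna[((i - 1L) %% nrow(sim$mirna)) + 1L, ]
    start <- loc$start + (i %% max(loc$end - loc$start - 22L, 1L))
    add_read(sprintf("mir_%06d", i), sub_seq(loc$chrom, start, 22L),
             data.frame(target = loc$chrom, start = start,
                        end = start + 22L, strand = "+",
                        stringsAsFactors = FALSE))
  }
  ## structural ncRNA reads: 25 nt from rRNA/tRNA/... loci
  if (comp$n_ncrna > 0 && !is.null(sim$ncrna)) {
    for (i in seq_len(comp$n_ncrna)) {
      loc <- sim$ncrna[((i - 1L) %% nrow(sim$ncrna)) + 1L, ]
      start <- loc$start + (i %% max(loc$end - loc$start - 25L, 1L))
      add_read(sprintf("nc_%06d", i), sub_seq(loc$chrom, start, 25L),
               data.frame(target = loc$chrom, start = start,
                          end = start + 25L, strand = "+",
                          stringsAsFactors = FALSE))
    }
  }
  ## transposon piRNAs from the consensus; genome hits at every copy
  te_read <- function(te, i, sense) {
    len <- 24L + (i %% 5L)
    tlen <- sim$te_lengths[[te]]
    start <- (i * 37L) %% (tlen - len)
    s <- substr(sim$te_seqs[[te]], start + 1L, start + len)
    insert <- if (sense) s else revcomp(s)
    copies <- sim$te_copies[sim$te_copies$te == te, , drop = FALSE]
    ghits <- data.frame(target = copies$chrom,
                        start = copies$start + start,
                        end = copies$start + start + len,
                        strand = if (sense) "+" else "-",
                        stringsAsFactors = FALSE)
    thits <- data.frame(target = te, start = start, end = start + len,
                        strand = if (sense) "+" else "-",
                        stringsAsFactors = FALSE)
    list(insert = insert, ghits = ghits, thits = thits)
  }
  for (te in te_names) {
    for (i in seq_len(comp$te_antisense[[te]])) {
      r <- te_read(te, i, sense = FALSE)
      add_read(sprintf("pia_%s_%06d", te, i), r$insert, r$ghits, r$thits)
    }
    for (i in seq_len(comp$te_sense[[te]])) {
      r <- te_read(te, i, sense = TRUE)
      add_read(sprintf("pis_%s_%06d", te, i), r$insert, r$ghits, r$thits)
    }
  }
  ## locus-unique cluster piRNAs from non-repetitive cluster sequence
  for (cl in names(comp$cluster_unique)) {
    cdef <- sim$clusters[sim$clusters$name == cl, ][1L, ]
    copies <- sim$te_copies[sim$te_copies$cluster == cl, , drop = FALSE]
    free_from <- if (nrow(copies)) max(copies$end) else cdef$start
    for (i in seq_len(comp$cluster_unique[[cl]])) {
      len <- 25L + (i %% 4L)
      start <- free_from + 100L + (i * 11L) %% (cdef$end - free_from -
                                                  200L - len)
      add_read(sprintf("clu_%s_%06d", cl, i),
               sub_seq(cdef$chrom, start, len),
               data.frame(target = cdef$chrom, start = start,
                          end = start + len, strand = "+",
                          stringsAsFactors = FALSE))
    }
  }

  ids <- names(reads)
  wrap <- function(insert) {
    paste0(random_dna(scheme$random5), insert, random_dna(scheme$random3),
           barcode, scheme$linker3)
  }
  fastq <- setNames(vapply(unlist(reads), wrap, character(1)), ids)

  bind_hits <- function(lst) {
    if (!length(lst)) {
      return(as_alignments(data.frame(read_id = character(),
                                      target = character(),
                                      start = integer(), end = integer(),
                                      strand = character())[0, ]))
    }
    df <- do.call(rbind, lst)
    df$read_id <- rep(names(lst), vapply(lst, nrow, integer(1)))
    df$mismatches <- 0L
    df$read_length <- df$end - df$start
    as_alignments(df)
  }
  genome_aln <- bind_hits(genome_hits)
  te_aln <- bind_hits(te_hits)

  norm <- config$mirna_norm_target / comp$n_mirna
  expected <- list(
    norm_factor = norm,
    categories = c(mirna = comp$n_mirna,
                   filtered_ncrna = comp$n_ncrna,
                   pirna_candidate = sum(comp$te_antisense) +
                     sum(comp$te_sense) + sum(comp$cluster_unique),
                   other = 0L),
    te_antisense_norm = comp$te_antisense * norm * 1000 / sim$te_lengths,
    te_antisense_raw = comp$te_antisense,
    cluster_unique = comp$cluster_unique,
    cluster_unique_norm = comp$cluster_unique * norm)
  structure(list(fastq = fastq, genome_aln = genome_aln, te_aln = te_aln,
                 barcode = barcode, expected = expected, seed = seed),
            class = "sim_srna")
}

#' Simulate a subfamily-labeled protein alignment with planted signals
#'
#' Generates a family of aligned sequences sharing a random consensus,
#' with one planted fully discriminative column (the focal subfamily
#' carries one residue, all others a different one) and one planted
#' focal-only insertion column, plus a configurable number of
#' low-coverage columns gapped in most rows.
#'
#' @param n_focal,n_other Sequences in the focal and the remaining
#'   subfamilies.
#' @param width Number of ordinary (shared) columns.
#' @param n_lowcov Low-coverage columns (non-gap in 50% of rows).
#' @param seed Integer seed.
#' @return List with `msa` (a `subfamily_msa`) and `truth` (0-based
#'   indices `discriminative_column`, `insertion_column`,
#'   `lowcov_columns`).
#' @export
sim_msa <- function(n_focal = 5L, n_other = 12L, width = 40L,
                    n_lowcov = 3L, seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- n_focal + n_other
  cons <- sample(aa, width, replace = TRUE)
  m <- matrix(rep(cons, each = n), nrow = n)
  ## sprinkle neutral variation shared by both groups
  for (j in seq_len(width)) {
    flip <- sample(n, size = max(1L, n %/% 10L))
    m[flip, j] <- sample(aa, length(flip), replace = TRUE)
  }
  is_focal <- c(rep(TRUE, n_focal), rep(FALSE, n_other))
  ## planted discriminative column
  disc <- sample(width, 1L)
  pair <- sample(aa, 2L)
  m[is_focal, disc] <- pair[1]; m[!is_focal, disc] <- pair[2]
  ## planted focal-only insertion column
  ins_res <- sample(aa, 1L)
  ins_col <- ifelse(is_focal, ins_res, "-")
  ## low-coverage columns: non-gap in half the rows
  low <- replicate(n_lowcov, {
    col <- sample(aa, n, replace = TRUE)
    col[sample(n, n - floor(n * 0.5))] <- "-"
    col
  })
  ins_at <- sample(width + 1L, 1L) - 1L   # insert after this many cols
  full <- cbind(m[, seq_len(ins_at), drop = FALSE], ins_col,
                m[, setdiff(seq_len(width), seq_len(ins_at)),
                  drop = FALSE], low)
  disc_full <- if (disc <= ins_at) disc - 1L else disc
  seqs <- setNames(apply(full, 1L, paste, collapse = ""),
                   c(sprintf("focal_%02d", seq_len(n_focal)),
                     sprintf("other_%02d", seq_len(n_other))))
  labels <- setNames(ifelse(is_focal, "Rhino", "HP1"), names(seqs))
  list(msa = subfamily_msa(seqs, labels, "Rhino"),
       truth = list(discriminative_column = disc_full,
                    insertion_column = ins_at,
                    lowcov_columns = width + 1L - 1L + seq_len(n_lowcov)))
}
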