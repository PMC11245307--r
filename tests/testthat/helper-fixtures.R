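## Shared fixture builders. Everything is generated in code; no files.

aln_df <- function(read_id, target, start, end, strand = "+",
                   mismatches = 0L, n_best_hits = NULL, read_length = NULL) {
  df <- data.frame(read_id = read_id, target = target, start = start,
                   end = end, strand = strand, mismatches = mismatches,
                   stringsAsFactors = FALSE)
  if (!is.null(n_best_hits)) df$n_best_hits <- n_best_hits
  if (!is.null(read_length)) df$read_length <- read_length
  as_alignments(df)
}

## CA-trace structure resembling a small helical domain
helix_structure <- function(n = 30L, seed = 1L, jitter = 0) {
  set.seed(seed)
  t <- seq_len(n)
  at <- data.frame(chain = "A", resno = t, resid = "ALA",
                   atom_name = "CA", element = "C",
                   x = cos(0.6 * t) * 4 + rnorm(n, 0, jitter),
                   y = sin(0.6 * t) * 4 + rnorm(n, 0, jitter),
                   z = 1.5 * t + rnorm(n, 0, jitter),
                   occupancy = 1, stringsAsFactors = FALSE)
  structure(list(id = sprintf("helix%d", seed), atoms = at),
            class = "structure_model")
}

random_rigid <- function() {
  ## uniform-ish random rotation via QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = rnorm(3, 0, 10))
}

rigid_copy <- function(model, transform) {
  apply_transform(model, transform)
}

## Brute-force oracle for locus-unique cluster counting: enumerate every
## read's hit set against every cluster directly from the definitions.
oracle_cluster_count <- function(aln, clusters) {
  counts <- setNames(numeric(length(unique(clusters$name))),
                     unique(clusters$name))
  for (rid in unique(aln$read_id)) {
    hits <- aln[aln$read_id == rid, , drop = FALSE]
    p5 <- ifelse(hits$strand == "+", hits$start, hits$end - 1L)
    memb <- rep(NA_character_, nrow(hits))
    for (h in seq_len(nrow(hits))) {
      for (ci in seq_len(nrow(clusters))) {
        if (hits$target[h] == clusters$chrom[ci] &&
            p5[h] >= clusters$start[ci] && p5[h] < clusters$end[ci]) {
          memb[h] <- clusters$name[ci]
          break
        }
      }
    }
    if (!anyNA(memb) && length(unique(memb)) == 1L) {
      counts[memb[1]] <- counts[memb[1]] + 1
    }
  }
  counts
}

## Random small instance for the oracle-equivalence property
random_cluster_instance <- function(seed) {
  set.seed(seed)
  n_clusters <- sample(1:5, 1)
  clusters <- data.frame(
    chrom = sample(c("c1", "c2"), n_clusters, replace = TRUE),
    start = sample(seq(0, 9000, by = 1000), n_clusters),
    name = sprintf("K%d", seq_len(n_clusters)),
    stringsAsFactors = FALSE)
  clusters$end <- clusters$start + 800L
  n_reads <- sample(20:200, 1)
  rows <- lapply(seq_len(n_reads), function(i) {
    n_hits <- sample(1:4, 1)
    start <- sample(0:9900, n_hits, replace = TRUE)
    data.frame(read_id = sprintf("r%04d", i),
               target = sample(c("c1", "c2"), n_hits, replace = TRUE),
               start = start, end = start + 26L,
               strand = sample(c("+", "-"), n_hits, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  list(aln = as_alignments(do.call(rbind, rows)), clusters = clusters)
}

## Minimal hand-written PDB text (two models, altlocs, a water)
write_mini_pdb <- function(path) {
  lines <- c(
    "HEADER    TEST STRUCTURE",
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  CA AVAL A   2       3.900   1.600   0.500  0.40  0.00           C",
    "ATOM      5  CA BVAL A   2       3.800   1.500   0.400  0.60  0.00           C",
    "HETATM    6  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1      50.000  50.000  50.000  1.00  0.00           N",
    "ENDMDL",
    "END")
  writeLines(lines, path)
  path
}

empty_aln <- function() {
  as_alignments(data.frame(read_id = character(), target = character(),
                           start = integer(), end = integer(),
                           strand = character(), stringsAsFactors = FALSE))
}

## top substitution column: highest discrimination score outside columns
## flagged by the indel scan
top_substitution_column <- function(msa) {
  sc <- column_discrimination(msa)
  ind <- find_subfamily_indels(msa)
  sc <- sc[!(sc$column %in% ind$column), , drop = FALSE]
  sc$column[which.max(sc$score)]
}
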