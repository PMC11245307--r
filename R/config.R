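#' Pipeline configuration
#'
#' Bundles every tunable constant of the analysis in one validated object.
#' The defaults reproduce the study settings: 1-kb tiles, exclusion of tiles
#' with less than 25% mappability or more than a threefold deviation from
#' the median input signal, a pseudocount of 1 on depth-normalized counts,
#' the >23 nt read-length filter for transposon-consensus mapping, the
#' 23-29 nt piRNA length window, normalization to one million sequenced
#' microRNA reads, the twofold antisense-piRNA dependence cutoff, the 70%
#' alignment-column coverage threshold, and a 0.4 Angstrom clash tolerance.
#'
#' @param tile_size Tile width in bases.
#' @param mappability_min Minimum mappable fraction for a tile to be kept.
#' @param input_deviation_fold Fold deviation from the median input count
#'   (two-sided, strict) beyond which a tile is excluded.
#' @param ko_residual_log2_max Maximum tolerated log2 ChIP enrichment in a
#'   knockout library before a tile is flagged as residual signal.
#' @param pseudocount Pseudocount added to depth-normalized counts.
#' @param depth_scale Depth normalization target (reads per this many mapped
#'   reads; default one million).
#' @param te_min_read_length Minimum read length (bases) for
#'   transposon-consensus ChIP mapping; the default 24 implements the
#'   "longer than 23 nucleotides" rule.
#' @param pirna_length_range Inclusive length window (bases) classifying a
#'   read as a piRNA candidate.
#' @param mirna_norm_target Library size the microRNA normalization scales
#'   to.
#' @param dependence_fold Fold reduction in antisense piRNAs that calls an
#'   element dependent (boundary inclusive).
#' @param msa_min_column_coverage Minimum non-gap fraction for an alignment
#'   column to survive condensation.
#' @param clash_tolerance Tolerance (Angstrom) subtracted from the sum of
#'   van der Waals radii in clash detection.
#' @param rng_seed Integer seed used for every stochastic step.
#' @return An object of class `pipeline_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$tile_size
#' @export
pipeline_config <- function(tile_size = 1000L,
                            mappability_min = 0.25,
                            input_deviation_fold = 3.0,
                            ko_residual_log2_max = 1.0,
                            pseudocount = 1.0,
                            depth_scale = 1e6,
                            te_min_read_length = 24L,
                            pirna_length_range = c(23L, 29L),
                            mirna_norm_target = 1e6,
                            dependence_fold = 2.0,
                            msa_min_column_coverage = 0.70,
                            clash_tolerance = 0.4,
                            rng_seed = 1L) {
  cfg <- list(
    tile_size = as.integer(tile_size),
    mappability_min = mappability_min,
    input_deviation_fold = input_deviation_fold,
    ko_residual_log2_max = ko_residual_log2_max,
    pseudocount = pseudocount,
    depth_scale = depth_scale,
    te_min_read_length = as.integer(te_min_read_length),
    pirna_length_range = as.integer(pirna_length_range),
    mirna_norm_target = mirna_norm_target,
    dependence_fold = dependence_fold,
    msa_min_column_coverage = msa_min_column_coverage,
    clash_tolerance = clash_tolerance,
    rng_seed = as.integer(rng_seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    "tile_size must be >= 1" = cfg$tile_size >= 1L,
    "mappability_min must lie in [0, 1]" =
      cfg$mappability_min >= 0 && cfg$mappability_min <= 1,
    "input_deviation_fold must be > 1" = cfg$input_deviation_fold > 1,
    "dependence_fold must be > 1" = cfg$dependence_fold > 1,
    "pseudocount must be >= 0" = cfg$pseudocount >= 0,
    "depth_scale must be > 0" = cfg$depth_scale > 0,
    "pirna_length_range must be [min, max] with min <= max" =
      length(cfg$pirna_length_range) == 2L &&
        cfg$pirna_length_range[1] <= cfg$pirna_length_range[2],
    "mirna_norm_target must be > 0" = cfg$mirna_norm_target > 0,
    "msa_min_column_coverage must lie in (0, 1]" =
      cfg$msa_min_column_coverage > 0 && cfg$msa_min_column_coverage <= 1,
    "clash_tolerance must be >= 0" = cfg$clash_tolerance >= 0
  )
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Read a pipeline configuration from a key/value file
#'
#' Accepts either YAML or a flat `key = value` / `key: value` text file;
#' keys not present fall back to the defaults of [pipeline_config()].
#'
#' @param path Path to the configuration file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  kv <- list()
  for (ln in txt) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*[:=]\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3L) {
      val <- strsplit(m[3], "[,\\s]+")[[1]]
      num <- suppressWarnings(as.numeric(val))
      kv[[m[2]]] <- if (!anyNA(num)) num else val
    }
  }
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, kv[intersect(names(kv), known)])
}

#' Describe a sequencing library
#'
#' Light metadata record attached to count tables so that downstream
#' normalization can be checked against the library it came from.
#'
#' @param name Library identifier.
#' @param role One of `"chip"`, `"input"`, `"small_rna"`.
#' @param genotype Genotype label (e.g. `"w1118"`, `"rhinoKO"`).
#' @param tissue `"ovary"` or `"testis"`.
#' @param total_mapped_reads Total mapped reads; must be positive for any
#'   library used in normalization.
#' @return An object of class `library_meta`.
#' @export
library_meta <- function(name, role = c("chip", "input", "small_rna"),
                         genotype = "wildtype",
                         tissue = c("ovary", "testis"),
                         total_mapped_reads = NA_real_) {
  role <- match.arg(role)
  tissue <- match.arg(tissue)
  if (!is.na(total_mapped_reads) && total_mapped_reads <= 0) {
    stop("total_mapped_reads must be > 0 for library '", name, "'")
  }
  structure(list(name = name, role = role, genotype = genotype,
                 tissue = tissue, total_mapped_reads = total_mapped_reads),
            class = "library_meta")
}
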