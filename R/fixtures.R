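# Bundled synthetic strain layout.
#
# The engineered strain that motivates this package carries 83 loxPsym
# sites over all 16 yeast chromosomes (at least two per chromosome), which
# collapse to 75 distinct loci; its published summary statistics are a
# 2775-pair junction space splitting 210 intra- / 2565 inter-chromosomal
# and a ~145 kb mean distance between adjacent sites. The deposited site
# coordinates are not redistributed here; the bundled table is a SYNTHETIC
# stand-in that reproduces those summary statistics exactly (per-chromosome
# locus counts chosen to match the pair split, positions evenly spread to
# match the mean spacing) on the standard S288C chromosome lengths.

#' Synthetic 83-site strain layout
#'
#' @return a `lox_site_table` of 75 distinct loci (83 sites including
#'   co-located tandem copies) across 16 chromosomes.
#' @seealso [sparlox_genome()] for a matching toy genome.
#' @export
sparlox_sites <- function() {
  path <- system.file("extdata", "sparlox83_sites_synthetic.tsv",
                      package = "loxscan")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  st <- lox_site_table(df$site_id, df$chrom, df$position, df$copies)
  attr(st, "lox_seq") <- LOXPSYM_SEQ
  st
}

#' Standard yeast chromosome lengths and centromeres
#'
#' @return `list(lengths = named integer vector, centromeres =
#'   centromere_table)` on the S288C assembly coordinates.
#' @export
sparlox_karyotype <- function() {
  ext <- function(f) system.file("extdata", f, package = "loxscan")
  len <- utils::read.delim(ext("yeast_chrom_lengths.tsv"),
                           stringsAsFactors = FALSE)
  cen <- read_centromere_table(ext("yeast_centromeres.tsv"))
  list(lengths = stats::setNames(len$length, len$chrom), centromeres = cen)
}

#' Toy genome carrying the synthetic 83-site layout
#'
#' Builds random chromosomes of the standard yeast lengths and splices the
#' fixture's motifs in at its positions, so flank extraction and pool
#' construction run against a full-size (but synthetic) genome.
#'
#' @param seed RNG seed for the random chromosome sequences.
#' @param scale optional length scale factor in (0, 1] to shrink the
#'   genome (site positions scale accordingly; spacing statistics then no
#'   longer match the strain).
#' @return `list(genome =, sites =)` as from [insert_lox()].
#' @export
sparlox_genome <- function(seed = 1L, scale = 1) {
  sites <- sparlox_sites()
  kar <- sparlox_karyotype()
  lens <- pmax(1000L, as.integer(round(kar$lengths * scale)))
  sites$position <- pmax(3000L, as.integer(round(sites$position * scale)))
  # map post-insertion fixture positions back to pre-insertion coordinates
  pre <- sites
  for (cn in unique(pre$chrom)) {
    w <- which(pre$chrom == cn)
    w <- w[order(pre$position[w])]
    shift <- c(0L, cumsum(34L * pre$copies[w]))[seq_along(w)]
    pre$position[w] <- pre$position[w] - shift
  }
  base <- make_toy_genome(length(lens), unname(lens), gc = 0.38,
                         seed = seed, names = names(lens))
  insert_lox(base, pre[c("site_id", "chrom", "position", "copies")],
             min_gap = 1000L)
}
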