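# io_core: genome container, readers/writers, coordinate conventions,
# pipeline configuration.
#
# Conventions used throughout the package:
#   * internal interval arithmetic is 0-based half-open,
#   * all TSV reports expose 1-based inclusive positions,
#   * BED input stays 0-based half-open (the format's own convention),
#   * site positions in LoxSiteTable are 1-based (first base of the motif).

#' Construct a genome model
#'
#' A genome model is an ordered set of chromosome records, each with a name,
#' a haplotype label (so diploids can carry two homologs of one chromosome),
#' a topology (linear or circular) and an uppercase A/C/G/T/N sequence.
#'
#' @param names character vector of chromosome names.
#' @param seqs character vector of sequences (same length as `names`).
#' @param haplotype haplotype labels, recycled; default `"1"`.
#' @param topology `"linear"` or `"circular"`, recycled.
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(names, seqs, haplotype = "1", topology = "linear") {
  stopifnot(length(names) == length(seqs), length(seqs) > 0)
  haplotype <- rep_len(as.character(haplotype), length(names))
  topology <- rep_len(topology, length(names))
  stopifnot(all(topology %in% c("linear", "circular")))
  seqs <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(names[bad], collapse = ", "))
  if (any(nchar(seqs) == 0)) stop("empty sequence(s) not allowed")
  key <- paste(names, haplotype, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (name, haplotype) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(list(records = data.frame(name = as.character(names),
                                      haplotype = haplotype,
                                      topology = topology,
                                      stringsAsFactors = FALSE),
                 seq = as.list(seqs)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  len <- vapply(x$seq, nchar, integer(1))
  cat("genome_model with", nrow(x$records), "chromosome record(s),",
      format(sum(len), big.mark = ","), "bp total\n")
  df <- cbind(x$records, length = len)
  print(utils::head(df, 20), row.names = FALSE)
  if (nrow(df) > 20) cat("...\n")
  invisible(x)
}

#' Chromosome lengths of a genome model
#' @param genome a `genome_model`.
#' @return named integer vector (`name|haplotype` keys).
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(vapply(genome$seq, nchar, integer(1)),
                  paste(genome$records$name, genome$records$haplotype,
                        sep = "|"))
}

# index of a record; haplotype NULL matches a unique name
record_index <- function(genome, name, haplotype = NULL) {
  hit <- genome$records$name == name
  if (!is.null(haplotype)) hit <- hit & genome$records$haplotype == haplotype
  w <- which(hit)
  if (length(w) == 0)
    stop("no chromosome record ", name,
         if (!is.null(haplotype)) paste0(" (haplotype ", haplotype, ")"))
  if (length(w) > 1)
    stop("chromosome ", name, " is ambiguous; specify a haplotype")
  w
}

#' Read a genome from FASTA
#'
#' One chromosome per record; sequences are uppercased and validated against
#' the A/C/G/T/N alphabet. The record name is the first whitespace-delimited
#' word of the header.
#'
#' @param path path to a FASTA file.
#' @param haplotype haplotype label to assign to all records.
#' @return a [genome_model()].
#' @export
read_genome <- function(path, haplotype = "1") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path), # keep invalid letters

                 error = function(e)
                   stop("FASTA parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (length(ss) == 0) stop("no FASTA records in ", path)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  g <- genome_model(nm, as.character(ss), haplotype = haplotype)
  lox_log("read_genome: ", length(ss), " record(s), ",
          sum(chrom_lengths(g)), " bp from ", path)
  g
}

#' Write a genome model to FASTA
#' @param genome a `genome_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome$seq))
  names(ss) <- paste0(genome$records$name, " haplotype=",
                      genome$records$haplotype, " topology=",
                      genome$records$topology)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a loxPsym site table
#'
#' One row per distinct locus. `position` is the 1-based coordinate of the
#' first base of the loxPsym motif; co-located tandem copies are encoded in
#' `copies` (a locus with `copies = k` carries `k` adjacent 34-bp motifs).
#'
#' @param site_id unique locus identifiers (e.g. `"IV-5"`).
#' @param chrom chromosome names.
#' @param position 1-based motif start positions.
#' @param copies positive integer motif multiplicities (default 1).
#' @param genome optional `genome_model` to validate coordinates against.
#' @return a `lox_site_table` (a data frame), sorted by chromosome and
#'   position.
#' @export
lox_site_table <- function(site_id, chrom, position, copies = 1L,
                           genome = NULL) {
  df <- data.frame(site_id = as.character(site_id),
                   chrom = as.character(chrom),
                   position = as.integer(position),
                   copies = as.integer(rep_len(copies, length(site_id))),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$site_id))
    stop("duplicate site_id: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  if (anyDuplicated(df[c("chrom", "position")]))
    stop("duplicate chrom+position rows; encode co-located sites via 'copies'")
  if (any(df$copies < 1)) stop("copies must be positive")
  if (any(df$position < 1)) stop("positions must be >= 1")
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    cl <- vapply(df$chrom, function(cn) {
      w <- genome$records$name == cn
      if (!any(w)) stop("site chromosome not in genome: ", cn)
      max(nchar(unlist(genome$seq[w])))
    }, numeric(1))
    motif_end <- df$position + 34L * df$copies - 1L
    bad <- motif_end > cl
    if (any(bad))
      stop("site(s) beyond chromosome end: ",
           paste(df$site_id[bad], collapse = ", "))
  }
  df <- df[order(df$chrom, df$position), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("lox_site_table", "data.frame")
  df
}

#' Read a loxPsym site table from TSV
#'
#' Expects columns `site_id`, `chrom`, `position`, `copies`.
#'
#' @param path TSV path.
#' @param genome a `genome_model` used to validate coordinates.
#' @return a `lox_site_table`.
#' @export
read_site_table <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "chrom", "position", "copies")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  st <- lox_site_table(df$site_id, df$chrom, df$position, df$copies,
                       genome = genome)
  lox_log("read_site_table: ", sum(st$copies), " site(s) at ", nrow(st),
          " distinct locus/loci on ", length(unique(st$chrom)),
          " chromosome(s)")
  st
}

#' Read a BED file as an interval set
#'
#' 3+ column BED, 0-based half-open. Overlapping intervals are kept as-is;
#' membership tests downstream use any-overlap semantics.
#'
#' @param path BED path.
#' @return an `interval_set` data frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  keep <- !grepl("^(#|track|browser)", ln) & nzchar(ln)
  parts <- strsplit(ln[keep], "\t")
  if (any(lengths(parts) < 3))
    stop("BED line ", which(keep)[which(lengths(parts) < 3)[1]],
         ": fewer than 3 columns")
  df <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                   start = as.integer(vapply(parts, `[`, character(1), 2)),
                   end = as.integer(vapply(parts, `[`, character(1), 3)),
                   stringsAsFactors = FALSE)
  bad <- !(df$start < df$end) | is.na(df$start) | is.na(df$end)
  if (any(bad))
    stop("BED line ", which(keep)[which(bad)[1]],
         ": start must be < end (0-based half-open)")
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Construct a centromere table
#'
#' One centromere interval per chromosome, 1-based inclusive. Used to decide
#' whether two loci lie on the same chromosome arm.
#'
#' @param chrom chromosome names (unique).
#' @param cen_start,cen_end 1-based inclusive centromere bounds.
#' @param genome optional `genome_model` for bounds validation.
#' @return a `centromere_table` data frame.
#' @export
centromere_table <- function(chrom, cen_start, cen_end, genome = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   cen_start = as.integer(cen_start),
                   cen_end = as.integer(cen_end), stringsAsFactors = FALSE)
  if (anyDuplicated(df$chrom)) stop("one centromere entry per chromosome")
  if (any(df$cen_start > df$cen_end) || any(df$cen_start < 1))
    stop("invalid centromere interval(s)")
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    for (i in seq_len(nrow(df))) {
      w <- genome$records$name == df$chrom[i]
      if (!any(w)) stop("centromere chromosome not in genome: ", df$chrom[i])
      if (df$cen_end[i] > max(nchar(unlist(genome$seq[w]))))
        stop("centromere beyond chromosome end: ", df$chrom[i])
    }
  }
  class(df) <- c("centromere_table", "data.frame")
  df
}

#' Read a centromere table from TSV (columns chrom, cen_start, cen_end)
#' @inheritParams read_site_table
#' @return a `centromere_table`.
#' @export
read_centromere_table <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "cen_start", "cen_end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("centromere table lacks column(s): ", paste(miss, collapse = ", "))
  centromere_table(df$chrom, df$cen_start, df$cen_end, genome = genome)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters shared by the junction-detection and CNV
#' stages. `flank_len` values outside the standard set
#' \{500, 1000, 1500, 2500\} bp are allowed but trigger a warning.
#'
#' @param flank_len flank length (bp) used for the junction reference pool.
#' @param lox_seq recombination site motif; must equal its own reverse
#'   complement.
#' @param max_lox_edits maximum edit distance when scanning reads for the
#'   motif.
#' @param min_flank_cov minimum aligned fraction of each flank for a
#'   junction call.
#' @param min_score_margin minimum score gap between the best and runner-up
#'   pool entry (in alignment score units: match +1, mismatch -1, gap open
#'   -2, gap extend -1).
#' @param min_flank shortest usable flank (bp); loci truncated below this on
#'   both sides are excluded from the pool.
#' @param cnv_window flank window (bp) for depth-based copy-number calls.
#' @param cnv_max_iter,cnv_tol iteration controls for the iterative CNV
#'   scaling.
#' @param seed optional RNG seed recorded with the configuration.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(flank_len = 1000L, lox_seq = LOXPSYM_SEQ,
                            max_lox_edits = 4L, min_flank_cov = 0.5,
                            min_score_margin = 20, min_flank = 200L,
                            cnv_window = 2000L, cnv_max_iter = 20L,
                            cnv_tol = 0.01, seed = NULL) {
  if (!flank_len %in% c(500L, 1000L, 1500L, 2500L))
    warning("non-standard flank_len ", flank_len,
            " (standard: 500, 1000, 1500, 2500)")
  if (!identical(toupper(lox_seq), dna_revcomp(lox_seq)))
    stop("lox_seq must be palindromic (equal to its own reverse complement)")
  stopifnot(max_lox_edits >= 0, min_flank_cov > 0, min_flank_cov <= 1,
            min_score_margin >= 0, min_flank > 0, cnv_window > 0)
  structure(list(flank_len = as.integer(flank_len),
                 lox_seq = toupper(lox_seq),
                 max_lox_edits = as.integer(max_lox_edits),
                 min_flank_cov = min_flank_cov,
                 min_score_margin = min_score_margin,
                 min_flank = as.integer(min_flank),
                 cnv_window = as.integer(cnv_window),
                 cnv_max_iter = as.integer(cnv_max_iter),
                 cnv_tol = cnv_tol, seed = seed),
            class = "pipeline_config")
}

#' Write a tabular result as a deterministic TSV report
#'
#' Numeric columns are written at 6 significant digits; rows are ordered by
#' the given sort key (default: all columns, left to right), so identical
#' inputs always yield byte-identical files. Position columns produced by
#' this package are 1-based inclusive.
#'
#' @param table a data frame.
#' @param path output path.
#' @param sort_by column names to sort by; `NULL` sorts by all columns.
#' @return the path, invisibly.
#' @export
write_report <- function(table, path, sort_by = NULL) {
  if (is.null(table)) stop("table must be non-null")
  df <- as.data.frame(table)
  if (nrow(df) > 0) {
    key <- sort_by %||% names(df)
    ord <- do.call(order, unname(df[key]))
    df <- df[ord, , drop = FALSE]
  }
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], 6)
  con <- file(path, open = "wb") # fixed EOL across platforms
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Re-read a TSV report written by [write_report()]
#' @param path report path.
#' @return a data frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# 0-based half-open <-> 1-based inclusive interval conversion
to_1based <- function(df) transform(df, start = start + 1L)
to_0based <- function(df) transform(df, start = start - 1L)
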