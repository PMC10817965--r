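# shared fixtures and independent oracles, built in code at test time

options(loxscan.verbose = "quiet")

# small genome with evenly spread loci; returns list(genome, sites, base)
tiny_lox_genome <- function(lens = c(120000, 90000), n_per = c(2, 2),
                            seed = 101) {
  g <- make_toy_genome(length(lens), lens, seed = seed)
  pos <- unlist(lapply(seq_along(lens), function(i)
    round(seq(0.15, 0.85, length.out = n_per[i]) * lens[i])))
  spec <- data.frame(chrom = rep(g$records$name, n_per), position = pos)
  c(insert_lox(g, spec), list(base = g))
}

# random counts table over n loci / all pairs, for formula properties
rand_counts_table <- function(n = 6, lambda = 8) {
  loci <- sprintf("S%02d", seq_len(n))
  per_site <- data.frame(site_id = loci,
                         n_norm = rpois(n, lambda),
                         n_re = 0, stringsAsFactors = FALSE)
  pr <- utils::combn(n, 2)
  n_re <- rpois(ncol(pr), lambda / 4)
  per_pair <- data.frame(site_a = loci[pr[1, ]], site_b = loci[pr[2, ]],
                         n_re = n_re, stringsAsFactors = FALSE)
  per_pair <- per_pair[per_pair$n_re > 0, , drop = FALSE]
  for (i in seq_len(nrow(per_pair))) {
    a <- match(per_pair$site_a[i], loci); b <- match(per_pair$site_b[i], loci)
    per_site$n_re[a] <- per_site$n_re[a] + per_pair$n_re[i]
    per_site$n_re[b] <- per_site$n_re[b] + per_pair$n_re[i]
  }
  counts_table(per_site, per_pair)
}

# full-DP edit distance (unit costs), the oracle for the bit-parallel scan
edit_distance_dp <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  prev <- 0:length(b)
  for (i in seq_along(a)) {
    cur <- c(i, numeric(length(b)))
    for (j in seq_along(b))
      cur[j + 1] <- min(prev[j] + (a[i] != b[j]), prev[j + 1] + 1,
                        cur[j] + 1)
    prev <- cur
  }
  prev[length(b) + 1]
}

# brute-force junction oracle: exact string search of every pool entry in
# every read (both strands); returns data.frame(read_id, motif_offset0,
# junction_id)
brute_force_junctions <- function(reads, pool) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  entries <- junction_seq(pool)
  flank_len <- pool$flank_len
  ss <- Biostrings::DNAStringSet(unname(reads))
  names(ss) <- names(reads)
  out <- list()
  for (j in seq_along(entries)) {
    ent <- entries[[j]]
    for (pat in unique(c(ent, dna_revcomp(ent)))) {
      m <- Biostrings::vmatchPattern(pat, ss)
      hit <- which(lengths(m) > 0)
      for (r in hit) {
        st <- Biostrings::startIndex(m)[[r]]
        for (p in st) {
          # 0-based motif offset inside the read
          left_len <- if (pat == ent) flank_len else
            nchar(ent) - flank_len - 34L
          out[[length(out) + 1]] <-
            data.frame(read_id = names(reads)[r],
                       motif_offset0 = p - 1L + left_len,
                       junction_id = names(entries)[j],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(0), motif_offset0 = integer(0),
                      junction_id = character(0)))
  unique(do.call(rbind, out))
}

# exhaustive arrangement oracle: all signed placements consistent with an
# observation set (canonicalised), for small numbers of segments
all_consistent_arrangements <- function(obs, copy_numbers,
                                        topology = "linear") {
  segs <- rep(as.integer(names(copy_numbers)), copy_numbers)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    unique(out)
  }
  obs_key <- function(o) paste(sort(paste(o$seg_a, o$end_a, o$seg_b,
                                          o$end_b, o$support)),
                               collapse = ";")
  want <- obs_key(obs)
  res <- character(0)
  for (p in perms(segs)) {
    n <- length(p)
    for (mask in seq_len(2^n) - 1L) {
      ori <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, "-", "+")
      o <- junctions_of_arrangement(p, ori, topology)
      if (identical(obs_key(o), want))
        res <- c(res, loxscan:::canon_arrangement(p, ori, topology))
    }
  }
  sort(unique(res))
}

# exact two-sided Mann-Whitney p by enumeration (no ties), the independent
# check for the wilcox-based group test
exact_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  cmb <- utils::combn(nx + ny, nx)
  vals <- c(x, y)
  us <- apply(cmb, 2, function(ix)
    sum(outer(vals[ix], vals[-ix], ">")) +
      0.5 * sum(outer(vals[ix], vals[-ix], "==")))
  mean(abs(us - nx * ny / 2) >= abs(U - nx * ny / 2) - 1e-12)
}

canon_of <- function(res) {
  a <- res$arrangement
  loxscan:::canon_arrangement(a$segment_id, a$orientation, res$topology)
}
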