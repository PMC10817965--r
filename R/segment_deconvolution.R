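# segment_deconvolution: reconstruct the order/orientation/topology of a
# rearranged chromosome's loxPsym-delimited segments from junction
# observations.
#
# A parental chromosome with m lox loci defines m + 1 segments, numbered
# left to right. Each segment has a head (left end in parental orientation)
# and a tail (right end). A junction observation joins two segment ends;
# the parental chromosome itself yields observations {k tail, k+1 head}.
# Reconstruction finds trails that place every segment copy exactly once
# while realising every observed junction — an Eulerian-path view of the
# segment multigraph, enumerated deterministically with backtracking.

#' Build a segment map from a chromosome's loxPsym sites
#'
#' @param genome the parental `genome_model`.
#' @param sites the parental `lox_site_table`.
#' @param chrom chromosome name.
#' @param haplotype optional haplotype restriction.
#' @return a `segment_map` data frame: `segment_id`, `start`, `end`
#'   (0-based half-open, motif excluded), `seq`; attributes `chrom`,
#'   `site_ids`.
#' @export
segment_map <- function(genome, sites, chrom, haplotype = NULL) {
  r <- record_index(genome, chrom, haplotype)
  s <- sites[sites$chrom == chrom, , drop = FALSE]
  s <- s[order(s$position), , drop = FALSE]
  if (nrow(s) < 1) stop("no loxPsym sites on ", chrom)
  chr <- genome$seq[[r]]
  mlen <- 34L * s$copies
  starts <- c(0L, s$position - 1L + mlen)      # 0-based
  ends <- c(s$position - 1L, nchar(chr))
  df <- data.frame(segment_id = seq_len(nrow(s) + 1L), start = starts,
                   end = ends, stringsAsFactors = FALSE)
  df$seq <- substring(chr, df$start + 1L, df$end)
  attr(df, "chrom") <- chrom
  attr(df, "site_ids") <- s$site_id
  class(df) <- c("segment_map", "data.frame")
  df
}

#' Marker (PCRTag-style) table
#'
#' Short recoded sequences that distinguish the synthetic chromosome copy
#' from its wild-type counterpart; used to partition reads before
#' deconvolution.
#'
#' @param marker_id marker names (each present once per variant).
#' @param variant `"synthetic"` or `"wildtype"`.
#' @param sequence marker sequences (>= 15 bp, all distinct).
#' @param segment_id segment carrying the marker.
#' @return a `marker_table` data frame.
#' @export
marker_table <- function(marker_id, variant, sequence, segment_id) {
  df <- data.frame(marker_id = as.character(marker_id),
                   variant = as.character(variant),
                   sequence = toupper(as.character(sequence)),
                   segment_id = as.integer(segment_id),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$variant %in% c("synthetic", "wildtype")))
  if (any(nchar(df$sequence) < 15)) stop("marker sequences must be >= 15 bp")
  if (anyDuplicated(df$sequence)) stop("marker sequences must be unique")
  for (m in unique(df$marker_id)) {
    v <- df[df$marker_id == m, ]
    if (nrow(v) == 2 && v$sequence[1] == v$sequence[2])
      stop("synthetic and wildtype sequences identical for marker ", m)
  }
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Partition reads by marker content
#'
#' A read is assigned to the variant whose marker hits (approximate match
#' at edit distance <= `max_edits`, both strands) strictly outnumber the
#' other variant's; ties and marker-free reads are unassigned.
#'
#' @param reads a `read_set` or named character vector.
#' @param markers a [marker_table()].
#' @param max_edits per-marker edit tolerance.
#' @return `list(synthetic =, wildtype =, unassigned =, tally =)`: read-id
#'   vectors and the per-read hit tally.
#' @export
partition_reads_by_markers <- function(reads, markers, max_edits = 2L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  pats <- c(markers$sequence, dna_revcomp(markers$sequence))
  vars <- rep(markers$variant, 2)
  tally <- t(vapply(reads, function(rd) {
    hits <- vapply(seq_along(pats), function(p)
      nrow(cpp_motif_scan(rd, pats[p], max_edits)), integer(1))
    c(synthetic = sum(hits[vars == "synthetic"]),
      wildtype = sum(hits[vars == "wildtype"]))
  }, integer(2)))
  assign <- ifelse(tally[, 1] > tally[, 2], "synthetic",
                   ifelse(tally[, 2] > tally[, 1], "wildtype",
                          "unassigned"))
  lox_log("partition_reads_by_markers: ",
          sum(assign == "synthetic"), " synthetic / ",
          sum(assign == "wildtype"), " wildtype / ",
          sum(assign == "unassigned"), " unassigned")
  list(synthetic = names(reads)[assign == "synthetic"],
       wildtype = names(reads)[assign == "wildtype"],
       unassigned = names(reads)[assign == "unassigned"],
       tally = data.frame(read_id = names(reads), tally,
                          assigned = assign, stringsAsFactors = FALSE))
}

# locus end -> segment end for the k-th lox locus on the chromosome
locus_end_to_segment_end <- function(site, side, site_ids) {
  k <- match(site, site_ids)
  if (is.na(k)) return(NULL)
  if (side == "u") list(seg = k, end = "tail") else
    list(seg = k + 1L, end = "head")
}

#' Observe segment-end junctions in reads
#'
#' Classifies loxPsym occurrences against the chromosome's own junction
#' pool and translates locus-end calls into segment-end observations.
#' Occurrences where only one side matches a segment flank (for example a
#' homology-mediated fusion to non-segment sequence) are reported as
#' unassigned rather than dropped.
#'
#' @param reads a `read_set` or named character vector (pre-partitioned if
#'   markers are in play).
#' @param genome parental `genome_model`.
#' @param sites parental `lox_site_table`.
#' @param chrom chromosome to deconvolve.
#' @param config a [pipeline_config()].
#' @return `list(observations =, unassigned =, calls =)`; observations have
#'   columns `seg_a`, `end_a`, `seg_b`, `end_b`, `support`.
#' @export
observe_junctions <- function(reads, genome, sites, chrom,
                              config = pipeline_config()) {
  s <- sites[sites$chrom == chrom, , drop = FALSE]
  s <- s[order(s$position), , drop = FALSE]
  if (nrow(s) < 2) stop("need >= 2 loci on ", chrom, " to observe junctions")
  attr(s, "lox_seq") <- attr(sites, "lox_seq") %||% LOXPSYM_SEQ
  class(s) <- class(sites)
  fl <- extract_flanks(genome, s, flank_len = config$flank_len,
                       min_flank = config$min_flank)
  pool <- build_junction_pool(fl)
  hits <- scan_lox_reads(reads, config$lox_seq, config$max_lox_edits)
  res <- classify_junctions(hits, reads, pool, config)
  calls <- res$calls
  site_ids <- s$site_id
  obs <- list()
  for (i in which(!is.na(calls$junction_id))) {
    e <- pool$entries[match(calls$junction_id[i],
                            pool$entries$junction_id), ]
    ea <- locus_end_to_segment_end(e$site_a, e$side_a, site_ids)
    eb <- locus_end_to_segment_end(e$site_b, e$side_b, site_ids)
    if (is.null(ea) || is.null(eb)) next
    obs[[length(obs) + 1]] <- data.frame(seg_a = ea$seg, end_a = ea$end,
                                         seg_b = eb$seg, end_b = eb$end,
                                         stringsAsFactors = FALSE)
  }
  observations <- if (length(obs)) {
    o <- do.call(rbind, obs)
    swap <- o$seg_b < o$seg_a | (o$seg_a == o$seg_b & o$end_a > o$end_b)
    tmp <- o[swap, c("seg_a", "end_a")]
    o[swap, c("seg_a", "end_a")] <- o[swap, c("seg_b", "end_b")]
    o[swap, c("seg_b", "end_b")] <- tmp
    agg <- stats::aggregate(list(support = rep(1L, nrow(o))),
                            o[c("seg_a", "end_a", "seg_b", "end_b")], sum)
    agg[order(agg$seg_a, agg$end_a, agg$seg_b, agg$end_b), , drop = FALSE]
  } else {
    data.frame(seg_a = integer(0), end_a = character(0),
               seg_b = integer(0), end_b = character(0),
               support = integer(0))
  }
  una <- calls[calls$class == "UNCLASSIFIED" &
                 xor(!is.na(calls$left_matched),
                     !is.na(calls$right_matched)), , drop = FALSE]
  rownames(observations) <- NULL
  list(observations = observations, unassigned = una, calls = calls)
}

#' Junction observations implied by a segment arrangement
#'
#' The inverse of [reconstruct()]: lists the segment-end junctions realised
#' by an ordered, oriented arrangement. Useful for simulations and for
#' verifying reconstructions.
#'
#' @param segment_id integer vector of placed segments, in order.
#' @param orientation `"+"`/`"-"` per placed segment.
#' @param topology `"linear"` or `"circular"`.
#' @return observation data frame (`seg_a`, `end_a`, `seg_b`, `end_b`,
#'   `support`).
#' @export
junctions_of_arrangement <- function(segment_id, orientation,
                                     topology = "linear") {
  n <- length(segment_id)
  stopifnot(length(orientation) == n, n >= 1)
  right_end <- ifelse(orientation == "+", "tail", "head")
  left_end <- ifelse(orientation == "+", "head", "tail")
  from <- seq_len(n - 1L); to <- from + 1L
  if (topology == "circular") { from <- c(from, n); to <- c(to, 1L) }
  if (!length(from))
    return(data.frame(seg_a = integer(0), end_a = character(0),
                      seg_b = integer(0), end_b = character(0),
                      support = integer(0)))
  o <- data.frame(seg_a = segment_id[from], end_a = right_end[from],
                  seg_b = segment_id[to], end_b = left_end[to],
                  stringsAsFactors = FALSE)
  swap <- o$seg_b < o$seg_a | (o$seg_a == o$seg_b & o$end_a > o$end_b)
  tmp <- o[swap, c("seg_a", "end_a")]
  o[swap, c("seg_a", "end_a")] <- o[swap, c("seg_b", "end_b")]
  o[swap, c("seg_b", "end_b")] <- tmp
  agg <- stats::aggregate(list(support = rep(1L, nrow(o))),
                          o[c("seg_a", "end_a", "seg_b", "end_b")], sum)
  agg <- agg[order(agg$seg_a, agg$end_a, agg$seg_b, agg$end_b), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# canonical string form of an arrangement, up to global flip (linear) or
# rotation + flip (circular)
canon_arrangement <- function(seg, ori, topology) {
  flip <- function(s, o) list(seg = rev(s),
                              ori = rev(ifelse(o == "+", "-", "+")))
  key <- function(s, o) paste(paste0(o, s), collapse = ",")
  if (topology == "linear") {
    f <- flip(seg, ori)
    min(key(seg, ori), key(f$seg, f$ori))
  } else {
    n <- length(seg)
    ks <- character(0)
    for (r in seq_len(n)) {
      idx <- c(r:n, seq_len(r - 1L))[seq_len(n)]
      ks <- c(ks, key(seg[idx], ori[idx]))
      f <- flip(seg[idx], ori[idx])
      ks <- c(ks, key(f$seg, f$ori))
    }
    min(ks)
  }
}

#' Reconstruct a segment arrangement from junction observations
#'
#' Builds the segment-end multigraph (each segment copy is an edge between
#' its head and tail; observed junctions are edges between ends) and
#' enumerates trails that place every segment copy exactly once and
#' realise every retained junction at least once. Topology is decided by
#' the free-end count: two ends untouched by junctions give a linear
#' arrangement (they become the chromosome termini), none gives a circle.
#' Distinct solutions (up to global flip, and rotation for circles) are
#' enumerated deterministically in sorted end order, up to a cap.
#'
#' @param observations observation data frame (see
#'   [junctions_of_arrangement()]); a `support` column is honoured.
#' @param copy_numbers named integer vector of segment copy numbers
#'   (names = segment ids); defaults to 1 for every segment present in
#'   `n_segments`.
#' @param n_segments number of parental segments (defaults to the largest
#'   segment id observed).
#' @param min_support discard junctions with fewer supporting reads
#'   (default 2; use 1 for error-free input).
#' @param max_alternatives enumeration cap.
#' @param anchor_segment segment held in `+` orientation (e.g. the
#'   centromere-containing segment); default: lowest placed segment id.
#' @return an `arrangement_result`: `list(arrangement =, topology =,
#'   alternatives =, ambiguous =)` where `arrangement` is a data frame
#'   (`order`, `segment_id`, `orientation`).
#' @export
reconstruct <- function(observations, copy_numbers = NULL,
                        n_segments = NULL, min_support = 2L,
                        max_alternatives = 16L, anchor_segment = NULL) {
  obs <- observations[observations$support >= min_support, , drop = FALSE]
  n_segments <- n_segments %||%
    max(c(obs$seg_a, obs$seg_b, length(copy_numbers)), 1L)
  cn <- rep(1L, n_segments)
  names(cn) <- as.character(seq_len(n_segments))
  if (!is.null(copy_numbers))
    cn[names(copy_numbers)] <- as.integer(copy_numbers)
  if (any(cn < 0)) stop("copy numbers must be >= 0")
  placed_total <- sum(cn)
  if (placed_total == 0) stop("no segment copies to place")
  # junction edge list between ends; ends keyed "seg:end"
  ek <- function(s, e) paste0(s, ":", e)
  jkey <- function(i) paste0(ek(obs$seg_a[i], obs$end_a[i]), "|",
                             ek(obs$seg_b[i], obs$end_b[i]))
  nj <- nrow(obs)
  # incidence per end
  inc <- if (nj > 0)
    table(c(ek(obs$seg_a, obs$end_a), ek(obs$seg_b, obs$end_b))) else
      table(character(0))
  free <- stats::setNames(c(cn, cn),
                          c(ek(seq_len(n_segments), "head"),
                            ek(seq_len(n_segments), "tail")))
  free[names(inc)] <- free[names(inc)] - as.vector(inc)
  free <- free[rep(cn, 2) > 0]
  over <- free[free < 0]
  if (length(over))
    stop("junction incidences exceed copy number at end(s): ",
         paste(names(over), collapse = ", "),
         " (missed duplication or spurious junction?)")
  n_free <- sum(free)
  topology <- if (n_free == 0) "circular" else "linear"
  if (topology == "linear" && n_free %% 2 == 1)
    stop("odd number of free segment ends (", n_free,
         "); junction set admits no arrangement: ",
         paste(names(free)[free > 0], collapse = ", "))
  # adjacency: end key -> indices of junctions incident
  adj <- list()
  for (i in seq_len(nj)) {
    a <- ek(obs$seg_a[i], obs$end_a[i]); b <- ek(obs$seg_b[i], obs$end_b[i])
    adj[[a]] <- c(adj[[a]], i)
    if (b != a) adj[[b]] <- c(adj[[b]], i)
  }
  other_end <- function(i, from_key) {
    a <- ek(obs$seg_a[i], obs$end_a[i]); b <- ek(obs$seg_b[i], obs$end_b[i])
    if (from_key == a) c(obs$seg_b[i], obs$end_b[i]) else
      c(obs$seg_a[i], obs$end_a[i])
  }
  results <- new.env()
  results$keys <- character(0)
  results$arr <- list()
  remaining <- cn
  used <- integer(nj)
  segs <- integer(placed_total); oris <- character(placed_total)
  start_key <- NULL
  dfs <- function(depth, cur_right) {
    if (length(results$keys) >= max_alternatives) return(invisible())
    if (depth == placed_total) {
      if (topology == "circular") {
        # need an unused-or-used junction closing back to the start end
        close_i <- adj[[cur_right]]
        okclose <- FALSE
        for (i in close_i) {
          oe <- other_end(i, cur_right)
          if (ek(oe[1], oe[2]) == start_key) {
            used[i] <<- used[i] + 1L
            if (all(used > 0)) okclose <- TRUE
            used[i] <<- used[i] - 1L
            if (okclose) break
          }
        }
        if (!okclose) return(invisible())
      } else {
        if (!all(used > 0)) return(invisible())
      }
      k <- canon_arrangement(segs, oris, topology)
      if (!k %in% results$keys) {
        results$keys <- c(results$keys, k)
        results$arr[[length(results$arr) + 1]] <-
          list(seg = segs, ori = oris)
      }
      return(invisible())
    }
    cand <- adj[[cur_right]]
    if (is.null(cand)) return(invisible())
    # prune: remaining junction obligations must be satisfiable
    for (i in cand) {
      oe <- other_end(i, cur_right)
      s2 <- as.integer(oe[1])
      if (remaining[s2] <= 0) next
      ori2 <- if (oe[2] == "head") "+" else "-"
      remaining[s2] <<- remaining[s2] - 1L
      used[i] <<- used[i] + 1L
      segs[depth + 1L] <<- s2; oris[depth + 1L] <<- ori2
      dfs(depth + 1L,
          ek(s2, if (ori2 == "+") "tail" else "head"))
      remaining[s2] <<- remaining[s2] + 1L
      used[i] <<- used[i] - 1L
    }
    invisible()
  }
  starts <- if (topology == "linear") {
    sk <- names(free)[free > 0]
    sk[order(sk)]
  } else {
    a <- anchor_segment %||% min(which(cn > 0))
    c(ek(a, "head"))
  }
  for (sk in starts) {
    parts <- strsplit(sk, ":", fixed = TRUE)[[1]]
    s1 <- as.integer(parts[1])
    if (remaining[s1] <= 0) next
    # the free end is the LEFT terminus of the trail
    ori1 <- if (parts[2] == "head") "+" else "-"
    if (topology == "circular") ori1 <- "+" # anchored start
    start_key <- sk
    remaining[s1] <- remaining[s1] - 1L
    segs[1] <- s1; oris[1] <- ori1
    dfs(1L, ek(s1, if (ori1 == "+") "tail" else "head"))
    remaining[s1] <- remaining[s1] + 1L
  }
  if (!length(results$arr))
    stop("no arrangement consistent with the junction observations; ",
         "free end slots: ",
         paste0(names(free)[free > 0], "(", free[free > 0], ")",
                collapse = ", "))
  # deterministic order; anchor orientation
  ord <- order(vapply(seq_along(results$arr), function(i)
    canon_arrangement(results$arr[[i]]$seg, results$arr[[i]]$ori,
                      topology), character(1)))
  arrs <- results$arr[ord]
  anchor <- anchor_segment %||% min(unlist(lapply(arrs, `[[`, "seg")))
  orient_arr <- function(a) {
    w <- which(a$seg == anchor)
    if (length(w) && a$ori[w[1]] == "-") {
      a$seg <- rev(a$seg)
      a$ori <- rev(ifelse(a$ori == "+", "-", "+"))
    }
    data.frame(order = seq_along(a$seg), segment_id = a$seg,
               orientation = a$ori, stringsAsFactors = FALSE)
  }
  arrs <- lapply(arrs, orient_arr)
  structure(list(arrangement = arrs[[1]], topology = topology,
                 alternatives = arrs, ambiguous = length(arrs) > 1),
            class = "arrangement_result")
}

#' @export
print.arrangement_result <- function(x, ...) {
  a <- x$arrangement
  cat("arrangement (", x$topology, "): ",
      paste0(a$orientation, a$segment_id, collapse = " "), "\n", sep = "")
  if (x$ambiguous)
    cat("ambiguous:", length(x$alternatives), "alternative(s)\n")
  invisible(x)
}

#' Write an arrangement as TSV
#' @param result an `arrangement_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_arrangement <- function(result, path) {
  df <- result$arrangement
  con <- file(path, open = "wb")
  writeLines(paste0("# topology: ", result$topology), con)
  close(con)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}
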