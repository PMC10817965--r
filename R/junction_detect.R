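# junction_detect: in-silico junction reference pool and classification of
# loxPsym-containing reads.
#
# Every distinct locus i contributes two flank "ends": u (the flank_len
# bases ending immediately before the motif, forward strand) and d (the
# flank_len bases starting immediately after it). A junction is an
# unordered pair of ends; its canonical sequence is
#   leftFlank + lox + rightFlank
# with leftFlank = U_a (side u) or revcomp(D_a) (side d) and rightFlank =
# D_b (side d) or revcomp(U_b) (side u), ends ordered by (locus, side).
# A junction sequence and its reverse complement denote the same entry.

#' Extract loxPsym flank sequences
#'
#' Flanks exclude the motif itself (all tandem copies at a locus). Flanks
#' truncated by a chromosome end are flagged; a locus is usable only when
#' both flanks reach `min_flank`.
#'
#' @param genome a `genome_model` (the parental reference).
#' @param sites the genome's `lox_site_table`.
#' @param flank_len flank length in bp.
#' @param min_flank minimum usable flank length.
#' @param haplotype restrict to records of this haplotype (default: the
#'   first record carrying each site's motif).
#' @return a `flank_library` data frame with columns `site_id`, `chrom`,
#'   `position`, `up_seq`, `down_seq`, `up_trunc`, `down_trunc`, `usable`.
#' @export
extract_flanks <- function(genome, sites, flank_len = 1000L,
                           min_flank = 200L, haplotype = NULL) {
  lox_seq <- attr(sites, "lox_seq") %||% LOXPSYM_SEQ
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    cn <- sites$chrom[i]
    cand <- which(genome$records$name == cn)
    if (!is.null(haplotype))
      cand <- cand[genome$records$haplotype[cand] == haplotype]
    r <- NA_integer_
    for (w in cand) {
      motif <- strrep(lox_seq, sites$copies[i])
      if (substr(genome$seq[[w]], sites$position[i],
                 sites$position[i] + nchar(motif) - 1L) == motif) {
        r <- w; break
      }
    }
    if (is.na(r))
      stop("motif not found at site ", sites$site_id[i], " (", cn, ":",
           sites$position[i], ")")
    chr <- genome$seq[[r]]
    p <- sites$position[i]
    mlen <- 34L * sites$copies[i]
    u0 <- max(1L, p - flank_len)
    up <- substr(chr, u0, p - 1L)
    d1 <- p + mlen
    down <- substr(chr, d1, min(nchar(chr), d1 + flank_len - 1L))
    data.frame(site_id = sites$site_id[i], chrom = cn, position = p,
               up_seq = up, down_seq = down,
               up_trunc = nchar(up) < flank_len,
               down_trunc = nchar(down) < flank_len,
               stringsAsFactors = FALSE)
  })
  fl <- do.call(rbind, rows)
  fl$usable <- nchar(fl$up_seq) >= min_flank & nchar(fl$down_seq) >= min_flank
  if (any(!fl$usable))
    warning("excluding ", sum(!fl$usable),
            " locus/loci with both/either flank < ", min_flank, " bp: ",
            paste(fl$site_id[!fl$usable], collapse = ", "))
  attr(fl, "flank_len") <- as.integer(flank_len)
  attr(fl, "lox_seq") <- lox_seq
  class(fl) <- c("flank_library", "data.frame")
  fl
}

#' Build the in-silico junction reference pool
#'
#' For L usable loci the pool holds L parental (normal) entries and
#' 4 * choose(L, 2) novel entries: every unordered pair of distinct loci in
#' all four end combinations. Same-locus self-pairs (\{u_i, u_i\},
#' \{d_i, d_i\}) are excluded by default, so pair accounting matches
#' choose(L, 2); enable them to study excision circles read back onto one
#' locus. Entry sequences are composed on demand ([junction_seq()]), so
#' building the pool is combinatorial bookkeeping only.
#'
#' @param flanks a `flank_library`.
#' @param include_self include same-end self-pair entries.
#' @return a `junction_pool`.
#' @export
build_junction_pool <- function(flanks, include_self = FALSE) {
  fl <- flanks[flanks$usable, , drop = FALSE]
  L <- nrow(fl)
  if (L < 2) stop("need >= 2 usable loci to build a junction pool")
  loci <- fl$site_id
  normal <- data.frame(site_a = loci, side_a = "u", site_b = loci,
                       side_b = "d", class = "normal",
                       stringsAsFactors = FALSE)
  pr <- utils::combn(L, 2)
  combos <- expand.grid(sa = c("u", "d"), sb = c("u", "d"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  novel <- data.frame(
    site_a = rep(loci[pr[1, ]], each = 4),
    side_a = rep(combos$sa, ncol(pr)),
    site_b = rep(loci[pr[2, ]], each = 4),
    side_b = rep(combos$sb, ncol(pr)),
    class = "novel", stringsAsFactors = FALSE)
  ent <- rbind(normal, novel)
  if (include_self) {
    selfs <- data.frame(site_a = rep(loci, each = 2),
                        side_a = rep(c("u", "d"), L),
                        site_b = rep(loci, each = 2),
                        side_b = rep(c("u", "d"), L),
                        class = "novel", stringsAsFactors = FALSE)
    ent <- rbind(ent, selfs)
  }
  # canonical end order and deterministic ids
  oi <- match(ent$site_a, loci); oj <- match(ent$site_b, loci)
  swap <- oj < oi | (oi == oj & ent$side_a == "d" & ent$side_b == "u")
  tmp <- ent[swap, c("site_a", "side_a")]
  ent[swap, c("site_a", "side_a")] <- ent[swap, c("site_b", "side_b")]
  ent[swap, c("site_b", "side_b")] <- tmp
  ent <- ent[order(match(ent$site_a, loci), ent$side_a,
                   match(ent$site_b, loci), ent$side_b), , drop = FALSE]
  ent$junction_id <- paste0(ent$site_a, ":", ent$side_a, "|", ent$site_b,
                            ":", ent$side_b)
  rownames(ent) <- NULL
  n_pairs <- ncol(pr)
  structure(list(entries = ent, flanks = fl,
                 lox_seq = attr(flanks, "lox_seq"),
                 flank_len = attr(flanks, "flank_len"),
                 n_loci = L, n_pairs = n_pairs),
            class = "junction_pool")
}

#' @export
print.junction_pool <- function(x, ...) {
  cat("junction_pool:", x$n_loci, "loci,", x$n_pairs, "site pairs,",
      nrow(x$entries), "entries (", sum(x$entries$class == "normal"),
      "normal +", sum(x$entries$class == "novel"), "novel ), flank_len",
      x$flank_len, "\n")
  invisible(x)
}

# left/right flank sequence of an end, in junction reading orientation
end_flank_seq <- function(pool, site, side, role = c("left", "right")) {
  role <- match.arg(role)
  i <- match(site, pool$flanks$site_id)
  if (role == "left") {
    if (side == "u") pool$flanks$up_seq[i] else
      dna_revcomp(pool$flanks$down_seq[i])
  } else {
    if (side == "d") pool$flanks$down_seq[i] else
      dna_revcomp(pool$flanks$up_seq[i])
  }
}

#' Compose junction entry sequences
#' @param pool a `junction_pool`.
#' @param junction_id entry ids; default all.
#' @return named character vector of sequences.
#' @export
junction_seq <- function(pool, junction_id = NULL) {
  ent <- pool$entries
  if (!is.null(junction_id))
    ent <- ent[match(junction_id, ent$junction_id), , drop = FALSE]
  left <- vapply(seq_len(nrow(ent)), function(k)
    end_flank_seq(pool, ent$site_a[k], ent$side_a[k], "left"), character(1))
  right <- vapply(seq_len(nrow(ent)), function(k)
    end_flank_seq(pool, ent$site_b[k], ent$side_b[k], "right"), character(1))
  stats::setNames(paste0(left, pool$lox_seq, right), ent$junction_id)
}

#' Write the junction pool as FASTA with structured headers
#'
#' Headers are `junction_id|siteA:side|siteB:side|class`.
#' @param pool a `junction_pool`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
pool_fasta <- function(pool, path) {
  seqs <- junction_seq(pool)
  ent <- pool$entries
  hdr <- paste0(ent$junction_id, "|", ent$site_a, ":", ent$side_a, "|",
                ent$site_b, ":", ent$side_b, "|", ent$class)
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Scan reads for loxPsym occurrences
#'
#' Reports all non-overlapping approximate occurrences of the (palindromic)
#' motif within each read, best occurrence first per overlap group; strand
#' scanning is redundant because the motif equals its own reverse
#' complement.
#'
#' @param reads a `read_set` or named character vector.
#' @param lox_seq motif (palindromic).
#' @param max_lox_edits maximum edit distance.
#' @return a `lox_hits` data frame: `read_id`, `occurrence`, `offset`
#'   (0-based motif start), `end` (0-based exclusive), `edits`.
#' @export
scan_lox_reads <- function(reads, lox_seq = LOXPSYM_SEQ,
                           max_lox_edits = 4L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  if (!identical(toupper(lox_seq), dna_revcomp(lox_seq)))
    stop("lox_seq must be palindromic")
  hits <- lapply(seq_along(reads), function(i) {
    h <- cpp_motif_scan(reads[[i]], lox_seq, max_lox_edits)
    if (nrow(h) == 0) return(NULL)
    data.frame(read_id = names(reads)[i], occurrence = seq_len(nrow(h)),
               offset = h$start, end = h$end, edits = h$edits,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), hits))
  if (is.null(out))
    out <- data.frame(read_id = character(0), occurrence = integer(0),
                      offset = integer(0), end = integer(0),
                      edits = integer(0))
  lox_log("scan_lox_reads: ", nrow(out), " occurrence(s) in ",
          length(unique(out$read_id)), " of ", length(reads), " read(s)")
  class(out) <- c("lox_hits", "data.frame")
  out
}

# candidate tables for per-end scoring (built once per pool)
pool_candidates <- function(pool) {
  fl <- pool$flanks
  left <- data.frame(site = rep(fl$site_id, 2),
                     side = rep(c("u", "d"), each = nrow(fl)),
                     seq = c(fl$up_seq, dna_revcomp(fl$down_seq)),
                     len = c(nchar(fl$up_seq), nchar(fl$down_seq)),
                     stringsAsFactors = FALSE)
  right <- data.frame(site = rep(fl$site_id, 2),
                      side = rep(c("d", "u"), each = nrow(fl)),
                      seq = c(fl$down_seq, dna_revcomp(fl$up_seq)),
                      len = c(nchar(fl$down_seq), nchar(fl$up_seq)),
                      stringsAsFactors = FALSE)
  list(left = left, right = right)
}

# score one read context against candidate ends; anchored at the lox
# boundary. side = "left": context and flanks anchored at their right ends
# (direct); side = "right": reverse both. Returns data.frame for the
# seed-shortlisted candidates.
score_side <- function(context, cand, idx, reversed, band, min_seed = 4L,
                       seed_frac = 0.4) {
  q <- if (reversed) str_rev(context) else context
  hits <- cpp_seed_hits(q, idx)
  top <- max(hits)
  if (top < min_seed) return(NULL)
  sel <- which(hits >= max(min_seed, seed_frac * top))
  refs <- if (reversed) str_rev(cand$seq[sel]) else cand$seq[sel]
  al <- cpp_anchor_align(q, refs, band, 1, -1, -2, -1)
  data.frame(cand = sel, site = cand$site[sel], side = cand$side[sel],
             score = al[, 1], cov = al[, 2] / cand$len[sel],
             seed_hits = hits[sel], stringsAsFactors = FALSE)
}

#' Classify loxPsym read occurrences against the junction pool
#'
#' For each motif occurrence, the read context (up to `flank_len` bases on
#' each side of the motif) is scored against the candidate flank ends with
#' a banded affine anchored-overlap alignment, after a k-mer seed prefilter
#' discards ends sharing no diagonal-consistent seeds with the context.
#' Pool-entry scores are the sums of their two end scores (maximised over
#' the two read orientations). The best entry is called when its margin
#' over the runner-up reaches `min_score_margin` and both flanks are
#' covered to `min_flank_cov`; ties and thin contexts yield UNCLASSIFIED.
#' Each occurrence contributes at most one count; a read spanning several
#' occurrences contributes one count per occurrence.
#'
#' @param hits a `lox_hits` table from [scan_lox_reads()].
#' @param reads the scanned reads (`read_set` or named character vector).
#' @param pool a `junction_pool`.
#' @param config a [pipeline_config()].
#' @param min_seed minimum diagonal-consistent seed count for a candidate
#'   end to be alignable.
#' @return `list(calls =, counts =)`: per-occurrence `junction_call`s and
#'   the aggregated [counts_table()]. Calls carry per-side diagnostics
#'   (`left_matched`, `right_matched`) used by the deconvolution module's
#'   unassigned-junction report.
#' @export
classify_junctions <- function(hits, reads, pool,
                               config = pipeline_config(),
                               min_seed = 4L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  flank_len <- pool$flank_len
  need <- ceiling(config$min_flank_cov * flank_len)
  cand <- pool_candidates(pool)
  seed_k <- 13L
  idxL <- cpp_seed_index(cand$left$seq, seed_k)
  idxR <- cpp_seed_index(str_rev(cand$right$seq), seed_k)
  band <- max(50L, ceiling(0.25 * flank_len))
  ent <- pool$entries
  # entry lookup by either end order
  look <- c(stats::setNames(ent$junction_id,
                            paste0(ent$site_a, ":", ent$side_a, "|",
                                   ent$site_b, ":", ent$side_b)),
            stats::setNames(ent$junction_id,
                            paste0(ent$site_b, ":", ent$side_b, "|",
                                   ent$site_a, ":", ent$side_a)))
  calls <- vector("list", nrow(hits))
  for (h in seq_len(nrow(hits))) {
    rd <- reads[[hits$read_id[h]]]
    off <- hits$offset[h]; oend <- hits$end[h]
    lctx <- substr(rd, max(1L, off - flank_len + 1L), off)
    rctx <- substr(rd, oend + 1L, min(nchar(rd), oend + flank_len))
    base <- data.frame(read_id = hits$read_id[h],
                       occurrence = hits$occurrence[h],
                       junction_id = NA_character_, class = "UNCLASSIFIED",
                       score = NA_real_, margin = NA_real_,
                       cov_left = NA_real_, cov_right = NA_real_,
                       left_matched = NA_character_,
                       right_matched = NA_character_,
                       stringsAsFactors = FALSE)
    if (nchar(lctx) < need || nchar(rctx) < need) {
      calls[[h]] <- base # too close to a read end
      next
    }
    ls <- score_side(lctx, cand$left, idxL, FALSE, band, min_seed)
    rs <- score_side(rctx, cand$right, idxR, TRUE, band, min_seed)
    if (!is.null(ls) && nrow(ls))
      base$left_matched <- ls$site[which.max(ls$score)]
    if (!is.null(rs) && nrow(rs))
      base$right_matched <- rs$site[which.max(rs$score)]
    if (is.null(ls) || is.null(rs) || !nrow(ls) || !nrow(rs)) {
      calls[[h]] <- base
      next
    }
    # compose entry scores over all shortlisted left x right combinations
    combo <- expand.grid(il = seq_len(nrow(ls)), ir = seq_len(nrow(rs)),
                         KEEP.OUT.ATTRS = FALSE)
    ka <- paste0(ls$site[combo$il], ":", ls$side[combo$il])
    kb <- paste0(rs$site[combo$ir], ":", rs$side[combo$ir])
    jid <- unname(look[paste0(ka, "|", kb)])
    ok <- !is.na(jid)
    if (!any(ok)) {
      calls[[h]] <- base
      next
    }
    sc <- ls$score[combo$il] + rs$score[combo$ir]
    df <- data.frame(jid = jid[ok], sc = sc[ok], il = combo$il[ok],
                     ir = combo$ir[ok], stringsAsFactors = FALSE)
    agg <- df[order(df$jid, -df$sc), ]
    agg <- agg[!duplicated(agg$jid), , drop = FALSE] # best per entry
    agg <- agg[order(-agg$sc), , drop = FALSE]
    best <- agg[1, ]
    margin <- if (nrow(agg) > 1) best$sc - agg$sc[2] else Inf
    covl <- ls$cov[best$il]; covr <- rs$cov[best$ir]
    if (margin >= config$min_score_margin &&
        covl >= config$min_flank_cov && covr >= config$min_flank_cov) {
      e <- ent[match(best$jid, ent$junction_id), ]
      base$junction_id <- best$jid
      base$class <- e$class
      base$score <- best$sc
      base$margin <- margin
      base$cov_left <- covl; base$cov_right <- covr
    }
    calls[[h]] <- base
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(read_id = character(0), occurrence = integer(0),
               junction_id = character(0), class = character(0),
               score = numeric(0), margin = numeric(0),
               cov_left = numeric(0), cov_right = numeric(0),
               left_matched = character(0), right_matched = character(0))
  class(calls) <- c("junction_calls", "data.frame")
  counts <- counts_from_calls(calls, pool)
  lox_log("classify_junctions: ", sum(calls$class == "normal"), " normal, ",
          sum(calls$class == "novel"), " novel, ",
          sum(calls$class == "UNCLASSIFIED"), " unclassified")
  list(calls = calls, counts = counts)
}

#' Construct a counts table
#'
#' Per-locus normal/rearranged read counts and per-pair rearranged counts.
#' `Nall_i = 2 * Nnorm_i + Nre_i` (a normal read certifies both flanks of
#' its locus, a rearranged read one).
#'
#' @param per_site data frame with columns `site_id`, `n_norm`, `n_re`.
#' @param per_pair data frame with columns `site_a`, `site_b`, `n_re`
#'   (unordered pairs, one row each).
#' @return a `counts_table`.
#' @export
counts_table <- function(per_site, per_pair) {
  stopifnot(all(c("site_id", "n_norm", "n_re") %in% names(per_site)),
            all(c("site_a", "site_b", "n_re") %in% names(per_pair)))
  if (any(per_site$n_norm < 0) || any(per_site$n_re < 0) ||
      any(per_pair$n_re < 0)) stop("counts must be >= 0")
  per_site$n_all <- 2 * per_site$n_norm + per_site$n_re
  structure(list(per_site = per_site, per_pair = per_pair),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat("counts_table:", nrow(x$per_site), "loci,",
      sum(x$per_site$n_norm), "normal /", sum(x$per_pair$n_re),
      "rearranged counts over", sum(x$per_pair$n_re > 0),
      "active pair(s)\n")
  invisible(x)
}

counts_from_calls <- function(calls, pool) {
  loci <- pool$flanks$site_id
  n_norm <- n_re <- stats::setNames(numeric(length(loci)), loci)
  norm <- calls[calls$class == "normal", , drop = FALSE]
  if (nrow(norm)) {
    t1 <- table(pool$entries$site_a[match(norm$junction_id,
                                          pool$entries$junction_id)])
    n_norm[names(t1)] <- as.numeric(t1)
  }
  nov <- calls[calls$class == "novel", , drop = FALSE]
  pair <- data.frame(site_a = character(0), site_b = character(0),
                     n_re = numeric(0))
  if (nrow(nov)) {
    e <- pool$entries[match(nov$junction_id, pool$entries$junction_id), ]
    pk <- paste0(e$site_a, "\r", e$site_b)
    tp <- table(pk)
    parts <- strsplit(names(tp), "\r", fixed = TRUE)
    pair <- data.frame(site_a = vapply(parts, `[`, character(1), 1),
                       site_b = vapply(parts, `[`, character(1), 2),
                       n_re = as.numeric(tp), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(pair))) {
      n_re[pair$site_a[i]] <- n_re[pair$site_a[i]] + pair$n_re[i]
      n_re[pair$site_b[i]] <- n_re[pair$site_b[i]] + pair$n_re[i] *
        (if (pair$site_a[i] == pair$site_b[i]) 1 else 1)
      if (pair$site_a[i] == pair$site_b[i]) # self pair counts once more
        n_re[pair$site_a[i]] <- n_re[pair$site_a[i]] - pair$n_re[i]
    }
  }
  ct <- counts_table(data.frame(site_id = loci, n_norm = as.numeric(n_norm),
                                n_re = as.numeric(n_re),
                                stringsAsFactors = FALSE), pair)
  attr(ct, "n_unclassified") <- sum(calls$class == "UNCLASSIFIED")
  ct
}

#' Aggregate per-pair rearranged counts into a matrix keyed by locus
#' @param counts a `counts_table`.
#' @param loci locus order; default the per-site table order.
#' @return symmetric numeric matrix of `Nre_ij`.
#' @export
pair_count_matrix <- function(counts, loci = NULL) {
  loci <- loci %||% counts$per_site$site_id
  m <- matrix(0, length(loci), length(loci), dimnames = list(loci, loci))
  pp <- counts$per_pair
  for (i in seq_len(nrow(pp))) {
    a <- pp$site_a[i]; b <- pp$site_b[i]
    m[a, b] <- m[a, b] + pp$n_re[i]
    if (a != b) m[b, a] <- m[b, a] + pp$n_re[i]
  }
  m
}
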