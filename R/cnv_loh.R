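# cnv_loh: flank read depth, iterative copy-number estimation, loxPsym
# presence/LOH state calls, and rule-based SV hypotheses.
#
# Each locus contributes two regions: "up" (the cnv_window bases upstream
# of the motif) and "down" (the window downstream). Reads are assigned to
# regions by unique-k-mer matching against the parental window sequences
# (robust to reads clipped at junctions), and depth is mean covered bases
# per position, split by whether the read contains the motif.

#' Compute flank read depth around loxPsym loci
#'
#' @param reads a `read_set` or named character vector.
#' @param genome the parental reference `genome_model` (window sequences
#'   are taken from here).
#' @param sites the parental `lox_site_table`.
#' @param window window size in bp (2000 by default).
#' @param lox_seq motif used to split reads by lox content.
#' @param max_lox_edits motif scan tolerance.
#' @param k,min_hits unique-k-mer matching parameters.
#' @param haplotype restrict window extraction to records of this
#'   haplotype.
#' @return a `flank_depth_table`: `site_id`, `side`, `width`, `truncated`,
#'   `depth_total`, `depth_lox`, `depth_nolox`.
#' @export
compute_flank_depth <- function(reads, genome, sites, window = 2000L,
                                lox_seq = LOXPSYM_SEQ, max_lox_edits = 4L,
                                k = 16L, min_hits = 3L, haplotype = NULL) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  fl <- extract_flanks(genome, sites, flank_len = window, min_flank = 1L,
                       haplotype = haplotype)
  win <- data.frame(site_id = rep(fl$site_id, each = 2),
                    side = rep(c("up", "down"), nrow(fl)),
                    stringsAsFactors = FALSE)
  win$seq <- as.vector(rbind(fl$up_seq, fl$down_seq))
  win$width <- nchar(win$seq)
  win$truncated <- win$width < window
  hits <- scan_lox_reads(reads, lox_seq, max_lox_edits)
  is_lox <- names(reads) %in% hits$read_id
  dp <- cpp_window_depth(win$seq, unname(reads), is_lox, k, min_hits)
  out <- data.frame(site_id = win$site_id, side = win$side,
                    width = win$width, truncated = win$truncated,
                    depth_lox = dp$covered_lox / win$width,
                    depth_nolox = dp$covered_nolox / win$width,
                    stringsAsFactors = FALSE)
  out$depth_total <- out$depth_lox + out$depth_nolox
  class(out) <- c("flank_depth_table", "data.frame")
  out
}

#' Iterative copy-number estimation from relative flank depth
#'
#' Depth ratios r = sample / parent are scaled by a factor s estimated
#' iteratively: start from the median ratio, assign integer copy numbers
#' `CN = round(ploidy * r / s)` (half away from zero), then re-estimate s
#' as the median ratio over regions currently at the modal ploidy, until
#' assignments stabilise. Regions whose scaled ratio sits further than
#' `low_conf_band` from an integer are flagged low-confidence. The
#' procedure is invariant to uniform depth scaling, i.e. to sequencing
#' depth.
#'
#' @param sample_depth,parent_depth `flank_depth_table`s on the same
#'   regions.
#' @param ploidy parental copy number of a normal region (2 for diploids).
#' @param max_iter,tol iteration controls (relative change in s).
#' @param low_conf_band flag radius around integers.
#' @return a `cnv_calls` data frame: `site_id`, `side`, `ratio`, `cn`,
#'   `low_conf`; attribute `scale` holds the final s.
#' @export
iterative_cnv <- function(sample_depth, parent_depth, ploidy = 2L,
                          max_iter = 20L, tol = 0.01,
                          low_conf_band = 0.35) {
  key <- function(d) paste(d$site_id, d$side)
  m <- match(key(sample_depth), key(parent_depth))
  if (anyNA(m)) stop("sample and parent depth tables cover different regions")
  pd <- parent_depth[m, ]
  usable <- pd$depth_total > 0
  r <- rep(NA_real_, nrow(sample_depth))
  r[usable] <- sample_depth$depth_total[usable] / pd$depth_total[usable]
  s <- stats::median(r[usable])
  if (!is.finite(s) || s <= 0) stop("no usable regions for CNV scaling")
  cn_prev <- rep(-1L, length(r))
  for (it in seq_len(max_iter)) {
    cn <- as.integer(round_half_away(ploidy * r / s))
    anchor <- usable & !is.na(cn) & cn == ploidy
    s_new <- if (any(anchor)) stats::median(r[anchor]) else {
      warning("no region at ploidy ", ploidy, " in iteration ", it,
              "; falling back to the global median ratio")
      stats::median(r[usable])
    }
    stable <- identical(cn, cn_prev) || abs(s_new - s) <= tol * s
    s <- s_new
    cn_prev <- cn
    if (stable) break
  }
  cn <- as.integer(round_half_away(ploidy * r / s))
  cn[!usable] <- NA_integer_
  dev <- abs(ploidy * r / s - cn)
  out <- data.frame(site_id = sample_depth$site_id,
                    side = sample_depth$side, ratio = r, cn = cn,
                    low_conf = !is.na(dev) & dev > low_conf_band,
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- s
  attr(out, "ploidy") <- ploidy
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Call loxPsym presence state per locus
#'
#' Combines copy number, lox-split depth and junction calls into one state
#' per locus:
#' \describe{
#'   \item{absent}{no flank copies remain (CN 0 on both sides).}
#'   \item{rearranged}{novel junction calls touch the locus.}
#'   \item{intact_lox}{parental junction reads present and CN > 0.}
#'   \item{lox_lost}{the parent carried the motif but no read shows it,
#'     while flank depth persists — the loss-of-heterozygosity signature.}
#'   \item{wildtype_only}{flanks present, no motif reads, and the parent
#'     was lox-free in this context.}
#' }
#'
#' @param cn_calls a `cnv_calls` table.
#' @param counts a `counts_table` from junction classification.
#' @param parent_has_lox logical (recycled): whether the parental strain
#'   carried the motif at each locus. Default `TRUE`.
#' @return a `lox_status` data frame: `site_id`, `cn_up`, `cn_down`,
#'   `n_norm`, `n_re`, `state`, `low_conf`.
#' @export
call_lox_status <- function(cn_calls, counts, parent_has_lox = TRUE) {
  loci <- unique(cn_calls$site_id)
  parent_has_lox <- rep_len(parent_has_lox, length(loci))
  ps <- counts$per_site
  rows <- lapply(seq_along(loci), function(i) {
    s <- loci[i]
    up <- cn_calls[cn_calls$site_id == s & cn_calls$side == "up", ]
    dn <- cn_calls[cn_calls$site_id == s & cn_calls$side == "down", ]
    j <- match(s, ps$site_id)
    n_norm <- if (!is.na(j)) ps$n_norm[j] else 0
    n_re <- if (!is.na(j)) ps$n_re[j] else 0
    cn_up <- if (nrow(up)) up$cn[1] else NA_integer_
    cn_dn <- if (nrow(dn)) dn$cn[1] else NA_integer_
    cn_max <- max(c(cn_up, cn_dn), na.rm = TRUE)
    low <- any(c(up$low_conf, dn$low_conf))
    state <- if (n_re > 0) {
      if (is.finite(cn_max) && cn_max == 0) low <- TRUE # contradictory
      "rearranged"
    } else if (is.finite(cn_max) && cn_max == 0) {
      "absent"
    } else if (n_norm > 0) {
      "intact_lox"
    } else if (parent_has_lox[i]) {
      "lox_lost"
    } else {
      "wildtype_only"
    }
    data.frame(site_id = s, cn_up = cn_up, cn_down = cn_dn,
               n_norm = n_norm, n_re = n_re, state = state,
               low_conf = isTRUE(low), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lox_status", "data.frame")
  out
}

#' Rule-based structural-variant hypotheses
#'
#' Combines copy-number asymmetries with novel junction calls:
#' \itemize{
#'   \item intra-chromosomal junction with interior flank loss: deletion;
#'   \item inter-chromosomal junction, all four flank regions at ploidy:
#'     reciprocal translocation;
#'   \item inter-chromosomal junction with one region gained and a partner
#'     region lost: non-reciprocal translocation;
#'   \item junction with gains only: duplication insertion;
#'   \item uniform chromosome-wide CN shift: chromosome gain/loss.
#' }
#'
#' @param cn_calls a `cnv_calls` table.
#' @param calls a `junction_calls` table.
#' @param pool the `junction_pool` used for classification.
#' @param sites the parental `lox_site_table`.
#' @param min_support minimum reads per junction.
#' @return an `sv_hypotheses` data frame: `kind`, `sites`, `junctions`,
#'   `evidence`.
#' @export
infer_sv_hypotheses <- function(cn_calls, calls, pool, sites,
                                min_support = 2L) {
  ploidy <- attr(cn_calls, "ploidy") %||% 2L
  cn_of <- function(site, side)
    cn_calls$cn[cn_calls$site_id == site & cn_calls$side == side][1]
  hyp <- list()
  add <- function(kind, sts, junctions, evidence)
    hyp[[length(hyp) + 1]] <<- data.frame(kind = kind,
                                          sites = paste(sts, collapse = ","),
                                          junctions = paste(junctions,
                                                            collapse = ","),
                                          evidence = evidence,
                                          stringsAsFactors = FALSE)
  nov <- calls[calls$class == "novel", , drop = FALSE]
  if (nrow(nov)) {
    supp <- table(nov$junction_id)
    for (jid in names(supp)[supp >= min_support]) {
      e <- pool$entries[match(jid, pool$entries$junction_id), ]
      # the junction consumes flank (a, side_a) and (b, side_b); the
      # complementary flanks are the ones whose fate distinguishes kinds
      partner_region <- function(side) c(u = "down", d = "up")[[side]]
      ca <- sites$chrom[match(e$site_a, sites$site_id)]
      cb <- sites$chrom[match(e$site_b, sites$site_id)]
      cn4 <- c(cn_of(e$site_a, "up"), cn_of(e$site_a, "down"),
               cn_of(e$site_b, "up"), cn_of(e$site_b, "down"))
      if (anyNA(cn4)) next
      gains <- sum(cn4 > ploidy); losses <- sum(cn4 < ploidy)
      if (!is.na(ca) && !is.na(cb) && ca == cb) {
        # interior flanks of an intra pair
        ia <- cn_of(e$site_a, partner_region(e$side_a))
        ib <- cn_of(e$site_b, partner_region(e$side_b))
        if (!is.na(ia) && !is.na(ib) && (ia < ploidy || ib < ploidy)) {
          add("deletion", c(e$site_a, e$site_b), jid,
              sprintf("interior flank CN %d/%d < ploidy %d", ia, ib,
                      ploidy))
          next
        }
      }
      if (gains == 0 && losses == 0) {
        add("reciprocal_translocation", c(e$site_a, e$site_b), jid,
            sprintf("all four flank regions at ploidy %d", ploidy))
      } else if (gains > 0 && losses > 0) {
        add("non_reciprocal_translocation", c(e$site_a, e$site_b), jid,
            sprintf("%d flank region(s) gained, %d lost", gains, losses))
      } else if (gains > 0) {
        add("duplication_insertion", c(e$site_a, e$site_b), jid,
            sprintf("%d flank region(s) gained, none lost", gains))
      } else {
        add("deletion", c(e$site_a, e$site_b), jid,
            sprintf("%d flank region(s) lost", losses))
      }
    }
  }
  # chromosome-wide uniform shifts
  chrom_of <- sites$chrom[match(cn_calls$site_id, sites$site_id)]
  for (cn in unique(chrom_of[!is.na(chrom_of)])) {
    v <- cn_calls$cn[chrom_of == cn]
    v <- v[!is.na(v)]
    if (length(v) >= 2 && length(unique(v)) == 1 && v[1] != ploidy) {
      add(if (v[1] > ploidy) "chromosome_gain" else "chromosome_loss",
          cn, character(0),
          sprintf("uniform CN %d across %d region(s)", v[1], length(v)))
    }
  }
  out <- if (length(hyp)) do.call(rbind, hyp) else
    data.frame(kind = character(0), sites = character(0),
               junctions = character(0), evidence = character(0))
  class(out) <- c("sv_hypotheses", "data.frame")
  out
}
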