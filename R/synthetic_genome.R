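# synthetic_genome: toy genomes, loxPsym insertion, Cre-mediated events with
# a ground-truth log, diploid LOH/aneuploidy, and long-read simulation.
#
# Internally a chromosome carrying lox sites is held as a token list:
# sequence tokens interleaved with lox tokens. A lox token remembers which
# flank "end" sits on each of its sides, as a (site_id, side) label with
# side "u" = the locus' upstream flank, "d" = its downstream flank. Events
# rearrange tokens; junction identities then fall out of the labels, which
# is what makes the event log an exact oracle for junction detection.

# ---- end labels -----------------------------------------------------------

end_label <- function(site, side) c(site = site, side = side)

end_key <- function(e) paste0(e[["site"]], ":", e[["side"]])

# canonical unordered pair key "a:u|b:d"
junction_key <- function(e1, e2) {
  k <- sort(c(end_key(e1), end_key(e2)))
  paste(k, collapse = "|")
}

# ---- toy genome -----------------------------------------------------------

#' Generate a random toy genome
#'
#' I.i.d. bases with the requested GC content; A/T and C/G are each split
#' evenly. Reproducible for a given seed.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths chromosome lengths (bp), recycled to `n_chrom`.
#' @param gc GC fraction.
#' @param seed RNG seed.
#' @param names chromosome names; default `chrI`, `chrII`, ...
#' @return a [genome_model()].
#' @export
make_toy_genome <- function(n_chrom, lengths, gc = 0.38, seed = 1L,
                            names = NULL) {
  stopifnot(n_chrom >= 1, all(lengths > 0), gc > 0, gc < 1)
  lengths <- rep_len(as.integer(lengths), n_chrom)
  if (is.null(names)) names <- paste0("chr", chrom_roman(seq_len(n_chrom)))
  seqs <- with_seed(seed, lapply(lengths, cpp_random_dna, gc = gc))
  genome_model(names, unlist(seqs))
}

# ---- lox insertion --------------------------------------------------------

#' Insert loxPsym sites into a genome
#'
#' Positions refer to the pre-insertion genome: a site "at position p"
#' splices its motif(s) between bases p-1 and p, so downstream coordinates
#' shift by 34 bp per inserted copy. The returned site table refers to the
#' post-insertion genome.
#'
#' @param genome a `genome_model` (single haplotype).
#' @param spec either a data frame with columns `chrom`, `position` and
#'   optionally `site_id`, `copies`, or a list
#'   `list(n_loci =, min_per_chrom =, seed =)` asking for a random layout
#'   (uniform placement, extra loci allocated proportionally to chromosome
#'   length, minimum separation 2 * `min_gap`).
#' @param lox_seq the motif to splice in (palindromic).
#' @param min_gap warn when two insertions are closer than this (bp);
#'   also the minimum separation used by random layouts. Default 1000.
#' @return `list(genome =, sites =)` with the edited genome and its
#'   post-insertion `lox_site_table`.
#' @export
insert_lox <- function(genome, spec, lox_seq = LOXPSYM_SEQ, min_gap = 1000L) {
  if (is.list(spec) && !is.data.frame(spec)) {
    spec <- random_lox_layout(genome, n_loci = spec$n_loci,
                              min_per_chrom = spec$min_per_chrom %||% 2L,
                              seed = spec$seed %||% 1L, min_gap = min_gap)
  }
  spec <- as.data.frame(spec)
  if (is.null(spec$copies)) spec$copies <- 1L
  if (is.null(spec$site_id)) {
    spec <- spec[order(match(spec$chrom, genome$records$name),
                       spec$position), , drop = FALSE]
    idx <- stats::ave(seq_len(nrow(spec)), spec$chrom, FUN = seq_along)
    spec$site_id <- paste0(sub("^chr", "", spec$chrom), "-", idx)
  }
  lens <- vapply(genome$seq, nchar, integer(1))
  out_seq <- genome$seq
  pos_post <- integer(nrow(spec))
  for (r in seq_len(nrow(genome$records))) {
    cn <- genome$records$name[r]
    w <- which(spec$chrom == cn)
    if (!length(w)) next
    w <- w[order(spec$position[w])]
    p <- spec$position[w]
    if (any(p < 1 | p > lens[r] + 1))
      stop("insertion position outside chromosome ", cn)
    if (any(diff(p) < min_gap))
      warning("insertions closer than ", min_gap, " bp on ", cn)
    copies <- spec$copies[w]
    pieces <- character(2 * length(p) + 1)
    bnd <- c(1L, p, lens[r] + 1L)
    for (k in seq_along(p)) {
      pieces[2 * k - 1] <- substr(out_seq[[r]], bnd[k], bnd[k + 1] - 1L)
      pieces[2 * k] <- strrep(lox_seq, copies[k])
    }
    pieces[2 * length(p) + 1] <- substr(out_seq[[r]], bnd[length(p) + 1],
                                        lens[r])
    out_seq[[r]] <- paste(pieces, collapse = "")
    shift <- c(0L, cumsum(34L * copies))[seq_along(p)]
    pos_post[w] <- p + shift
  }
  g2 <- genome
  g2$seq <- out_seq
  sites <- lox_site_table(spec$site_id, spec$chrom, pos_post, spec$copies,
                          genome = g2)
  attr(sites, "lox_seq") <- toupper(lox_seq)
  list(genome = g2, sites = sites)
}

# random layout helper: >= min_per_chrom loci everywhere, remainder
# proportional to length, uniform positions away from ends
random_lox_layout <- function(genome, n_loci, min_per_chrom = 2L, seed = 1L,
                              min_gap = 1000L) {
  lens <- vapply(genome$seq, nchar, integer(1))
  nc <- length(lens)
  if (n_loci < nc * min_per_chrom)
    stop("n_loci too small for ", min_per_chrom, " loci per chromosome")
  with_seed(seed, {
    n_per <- rep(min_per_chrom, nc)
    extra <- n_loci - sum(n_per)
    if (extra > 0) {
      add <- table(factor(sample.int(nc, extra, replace = TRUE,
                                     prob = lens / sum(lens)),
                          levels = seq_len(nc)))
      n_per <- n_per + as.integer(add)
    }
    do.call(rbind, lapply(seq_len(nc), function(r) {
      lo <- max(min_gap, 2000L)
      hi <- lens[r] - lo
      repeat {
        p <- sort(sample(seq.int(lo, hi), n_per[r]))
        if (all(diff(p) >= 2L * min_gap)) break
      }
      data.frame(chrom = genome$records$name[r], position = p,
                 stringsAsFactors = FALSE)
    }))
  })
}

# ---- tokenisation ---------------------------------------------------------

# split a genome record into seq/lox tokens given the sites on it
tokenize_record <- function(seq, rec, sites, lox_seq) {
  s <- sites[sites$chrom == rec$name, , drop = FALSE]
  toks <- list()
  if (nrow(s) == 0) {
    toks[[1]] <- list(type = "seq", seq = seq)
  } else {
    s <- s[order(s$position), , drop = FALSE]
    motif_len <- 34L * s$copies
    ok <- vapply(seq_len(nrow(s)), function(k)
      substr(seq, s$position[k], s$position[k] + motif_len[k] - 1L) ==
        strrep(lox_seq, s$copies[k]), logical(1))
    if (!all(ok)) return(NULL) # record does not carry these sites
    cur <- 1L
    for (k in seq_len(nrow(s))) {
      toks[[length(toks) + 1]] <-
        list(type = "seq", seq = substr(seq, cur, s$position[k] - 1L))
      toks[[length(toks) + 1]] <-
        list(type = "lox", site = s$site_id[k], copies = s$copies[k],
             lend = end_label(s$site_id[k], "u"),
             rend = end_label(s$site_id[k], "d"))
      cur <- s$position[k] + motif_len[k]
    }
    toks[[length(toks) + 1]] <-
      list(type = "seq", seq = substr(seq, cur, nchar(seq)))
  }
  list(name = rec$name, haplotype = rec$haplotype, topology = rec$topology,
       tokens = toks)
}

tokenize_genome <- function(genome, sites, lox_seq = NULL) {
  lox_seq <- lox_seq %||% attr(sites, "lox_seq") %||% LOXPSYM_SEQ
  recs <- lapply(seq_len(nrow(genome$records)), function(r) {
    tr <- tokenize_record(genome$seq[[r]], genome$records[r, ], sites,
                          lox_seq)
    if (is.null(tr)) # homolog without the motifs: lox-free record
      tr <- list(name = genome$records$name[r],
                 haplotype = genome$records$haplotype[r],
                 topology = genome$records$topology[r],
                 tokens = list(list(type = "seq", seq = genome$seq[[r]])))
    tr
  })
  structure(list(records = recs, lox_seq = lox_seq), class = "tok_genome")
}

detokenize_genome <- function(tg) {
  nrec <- length(tg$records)
  names <- character(nrec); hap <- character(nrec); topo <- character(nrec)
  seqs <- character(nrec)
  site_rows <- list()
  for (r in seq_len(nrec)) {
    rec <- tg$records[[r]]
    names[r] <- rec$name; hap[r] <- rec$haplotype; topo[r] <- rec$topology
    off <- 0L
    parts <- character(length(rec$tokens))
    for (k in seq_along(rec$tokens)) {
      tok <- rec$tokens[[k]]
      if (tok$type == "seq") {
        parts[k] <- tok$seq
        off <- off + nchar(tok$seq)
      } else {
        site_rows[[length(site_rows) + 1]] <-
          data.frame(site_id = tok$site, chrom = rec$name,
                     position = off + 1L, copies = tok$copies,
                     haplotype = rec$haplotype, stringsAsFactors = FALSE)
        parts[k] <- strrep(tg$lox_seq, tok$copies)
        off <- off + 34L * tok$copies
      }
    }
    seqs[r] <- paste(parts, collapse = "")
  }
  genome <- genome_model(names, seqs, haplotype = hap, topology = topo)
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else NULL
  if (!is.null(sites) && anyDuplicated(sites$site_id))
    sites$site_id <- make.unique(sites$site_id, sep = "#")
  list(genome = genome, sites = sites)
}

# all junctions realised by lox tokens in the (final) token genome
token_junctions <- function(tg) {
  rows <- list()
  for (rec in tg$records) {
    for (tok in rec$tokens) {
      if (tok$type != "lox") next
      parental <- tok$lend[["site"]] == tok$rend[["site"]] &&
        tok$lend[["side"]] == "u" && tok$rend[["side"]] == "d"
      rows[[length(rows) + 1]] <-
        data.frame(key = junction_key(tok$lend, tok$rend),
                   site_a = tok$lend[["site"]], side_a = tok$lend[["side"]],
                   site_b = tok$rend[["site"]], side_b = tok$rend[["side"]],
                   class = if (parental) "normal" else "novel",
                   self_pair = tok$lend[["site"]] == tok$rend[["site"]] &&
                     tok$lend[["side"]] == tok$rend[["side"]],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(key = character(0), site_a = character(0),
                      side_a = character(0), site_b = character(0),
                      side_b = character(0), class = character(0),
                      self_pair = logical(0)))
  unique(do.call(rbind, rows))
}

# locate a site's lox token: c(record_index, token_index)
find_lox <- function(tg, site) {
  for (r in seq_along(tg$records)) {
    toks <- tg$records[[r]]$tokens
    for (k in seq_along(toks))
      if (toks[[k]]$type == "lox" && toks[[k]]$site == site)
        return(c(r, k))
  }
  stop("site ", site, " not present in current genome ",
       "(removed by an earlier event?)")
}

# ---- SV events ------------------------------------------------------------

#' Describe a structural-variant event
#'
#' @param kind one of `deletion`, `inversion`, `duplication`,
#'   `inverted_duplication`, `translocation_reciprocal`,
#'   `translocation_nonreciprocal`, `circularization`, `chrom_gain`,
#'   `chrom_loss`, `loh_conversion`.
#' @param sites character vector of one or two site ids (Cre-type events),
#'   or the site ids defining an LOH interval.
#' @param chrom chromosome name (aneuploidy events).
#' @param haplotype target haplotype label (diploid events).
#' @param ... kind-specific parameters (e.g. `direction` for
#'   `loh_conversion`: `"to_wildtype"` removes the lox allele,
#'   `"to_lox"` copies it onto the homolog).
#' @return an `sv_event` list.
#' @export
sv_event <- function(kind, sites = NULL, chrom = NULL, haplotype = NULL,
                     ...) {
  kinds <- c("deletion", "inversion", "duplication", "inverted_duplication",
             "translocation_reciprocal", "translocation_nonreciprocal",
             "circularization", "chrom_gain", "chrom_loss", "loh_conversion")
  kind <- match.arg(kind, kinds)
  structure(list(kind = kind, sites = sites, chrom = chrom,
                 haplotype = haplotype, params = list(...)),
            class = "sv_event")
}

new_event_log <- function() {
  structure(list(events = list(), junctions = list(), losses = character(0),
                 final_junctions = NULL), class = "event_log")
}

log_event <- function(log, ev, junctions, losses = character(0)) {
  i <- length(log$events) + 1L
  log$events[[i]] <- ev
  log$junctions[[i]] <- junctions # data.frame or NULL
  log$losses <- union(log$losses, losses)
  log
}

#' @export
print.event_log <- function(x, ...) {
  cat("event_log:", length(x$events), "event(s),",
      sum(vapply(x$junctions, function(j) if (is.null(j)) 0L else nrow(j),
                 integer(1))), "expected junction(s),",
      length(x$losses), "lost locus/loci\n")
  for (i in seq_along(x$events)) {
    ev <- x$events[[i]]
    cat(sprintf("  %2d. %-28s %s\n", i, ev$kind,
                paste(ev$sites %||% ev$chrom, collapse = " ~ ")))
  }
  invisible(x)
}

#' Expected junctions of an event log
#'
#' @param log an `event_log`.
#' @param surviving_only if `TRUE` (default), restrict to junctions still
#'   realised in the final genome (later events can destroy earlier
#'   junctions).
#' @param include_self include self-pair junctions (undetectable when the
#'   pool excludes self-pairs).
#' @return data frame of junction end pairs with a `key` column.
#' @export
expected_junctions <- function(log, surviving_only = TRUE,
                               include_self = FALSE) {
  jl <- Filter(Negate(is.null), log$junctions)
  df <- if (length(jl)) unique(do.call(rbind, jl)) else
    data.frame(key = character(0))
  if (surviving_only && !is.null(log$final_junctions))
    df <- df[df$key %in%
               log$final_junctions$key[log$final_junctions$class == "novel"],
             , drop = FALSE]
  if (!include_self && nrow(df)) df <- df[!df$self_pair, , drop = FALSE]
  rownames(df) <- NULL
  df
}

junction_row <- function(e1, e2) {
  data.frame(key = junction_key(e1, e2),
             site_a = e1[["site"]], side_a = e1[["side"]],
             site_b = e2[["site"]], side_b = e2[["side"]],
             self_pair = end_key(e1) == end_key(e2),
             stringsAsFactors = FALSE)
}

# site ids of lox tokens in a token sublist
sites_in_tokens <- function(toks) {
  unlist(lapply(toks, function(t) if (t$type == "lox") t$site else NULL)) %||%
    character(0)
}

# reverse-complement a token sublist (inversion interior)
rc_tokens <- function(toks) {
  out <- rev(toks)
  lapply(out, function(t) {
    if (t$type == "seq") {
      t$seq <- dna_revcomp(t$seq)
    } else {
      tmp <- t$lend; t$lend <- t$rend; t$rend <- tmp
    }
    t
  })
}

new_lox_token <- function(site, lend, rend, copies = 1L) {
  list(type = "lox", site = site, copies = copies, lend = lend, rend = rend)
}

# apply one Cre-type event to the token genome; returns list(tg, junctions,
# losses)
apply_one_event <- function(tg, ev) {
  k <- ev$kind
  if (k %in% c("deletion", "inversion", "duplication",
               "inverted_duplication", "circularization")) {
    a <- find_lox(tg, ev$sites[1]); b <- find_lox(tg, ev$sites[2])
    if (a[1] != b[1])
      stop(k, " sites must lie on one chromosome: ",
           paste(ev$sites, collapse = ", "))
    r <- a[1]
    ij <- sort(c(a[2], b[2]))
    toks <- tg$records[[r]]$tokens
    li <- toks[[ij[1]]]; lj <- toks[[ij[2]]]
    interior <- if (ij[2] - ij[1] > 1) toks[(ij[1] + 1):(ij[2] - 1)] else
      list()
    before <- if (ij[1] > 1) toks[1:(ij[1] - 1)] else list()
    after <- if (ij[2] < length(toks)) toks[(ij[2] + 1):length(toks)] else
      list()
    if (k == "deletion") {
      fused <- new_lox_token(li$site, li$lend, lj$rend)
      tg$records[[r]]$tokens <- c(before, list(fused), after)
      return(list(tg = tg, junctions = junction_row(li$lend, lj$rend),
                  losses = c(sites_in_tokens(interior), lj$site)))
    }
    if (k == "inversion") {
      li2 <- new_lox_token(li$site, li$lend, lj$lend, li$copies)
      lj2 <- new_lox_token(lj$site, li$rend, lj$rend, lj$copies)
      tg$records[[r]]$tokens <- c(before, list(li2), rc_tokens(interior),
                                  list(lj2), after)
      return(list(tg = tg,
                  junctions = rbind(junction_row(li$lend, lj$lend),
                                    junction_row(li$rend, lj$rend)),
                  losses = character(0)))
    }
    if (k == "duplication") {
      mid <- new_lox_token(paste0(li$site, "~", lj$site), lj$lend, li$rend)
      tg$records[[r]]$tokens <- c(before, list(li), interior, list(mid),
                                  interior, list(lj), after)
      return(list(tg = tg, junctions = junction_row(lj$lend, li$rend),
                  losses = character(0)))
    }
    if (k == "inverted_duplication") {
      mid <- new_lox_token(paste0(li$site, "~", lj$site), lj$lend, lj$lend)
      lj2 <- new_lox_token(lj$site, li$rend, lj$rend, lj$copies)
      tg$records[[r]]$tokens <- c(before, list(li), interior, list(mid),
                                  rc_tokens(interior), list(lj2), after)
      return(list(tg = tg,
                  junctions = rbind(junction_row(lj$lend, lj$lend),
                                    junction_row(li$rend, lj$rend)),
                  losses = character(0)))
    }
    if (k == "circularization") {
      join <- new_lox_token(li$site, lj$lend, li$rend)
      tg$records[[r]]$tokens <- c(list(join), interior)
      tg$records[[r]]$topology <- "circular"
      return(list(tg = tg, junctions = junction_row(lj$lend, li$rend),
                  losses = c(sites_in_tokens(before), sites_in_tokens(after),
                             lj$site)))
    }
  }
  if (k %in% c("translocation_reciprocal", "translocation_nonreciprocal")) {
    a <- find_lox(tg, ev$sites[1]); b <- find_lox(tg, ev$sites[2])
    if (a[1] == b[1])
      stop("translocation sites must lie on different chromosomes: ",
           paste(ev$sites, collapse = ", "))
    ra <- a[1]; rb <- b[1]
    ta <- tg$records[[ra]]$tokens; tb <- tg$records[[rb]]$tokens
    li <- ta[[a[2]]]; lj <- tb[[b[2]]]
    Pa <- if (a[2] > 1) ta[1:(a[2] - 1)] else list()
    Qa <- if (a[2] < length(ta)) ta[(a[2] + 1):length(ta)] else list()
    Pb <- if (b[2] > 1) tb[1:(b[2] - 1)] else list()
    Qb <- if (b[2] < length(tb)) tb[(b[2] + 1):length(tb)] else list()
    if (k == "translocation_reciprocal") {
      tg$records[[ra]]$tokens <-
        c(Pa, list(new_lox_token(li$site, li$lend, lj$rend)), Qb)
      tg$records[[rb]]$tokens <-
        c(Pb, list(new_lox_token(lj$site, lj$lend, li$rend)), Qa)
      return(list(tg = tg,
                  junctions = rbind(junction_row(li$lend, lj$rend),
                                    junction_row(lj$lend, li$rend)),
                  losses = character(0)))
    }
    # non-reciprocal: keep P_a + lox + Q_b; chromosome b and Q_a are lost
    lost <- c(sites_in_tokens(Qa), sites_in_tokens(Pb), lj$site)
    tg$records[[ra]]$tokens <-
      c(Pa, list(new_lox_token(li$site, li$lend, lj$rend)), Qb)
    tg$records[[rb]] <- NULL
    return(list(tg = tg, junctions = junction_row(li$lend, lj$rend),
                losses = lost))
  }
  if (k == "chrom_gain") {
    r <- which(vapply(tg$records, function(x)
      x$name == ev$chrom &&
        (is.null(ev$haplotype) || x$haplotype == ev$haplotype),
      logical(1)))
    if (length(r) != 1) stop("chrom_gain: need exactly one matching record")
    new <- tg$records[[r]]
    new$haplotype <- paste0(new$haplotype, "+")
    tg$records[[length(tg$records) + 1]] <- new
    return(list(tg = tg, junctions = NULL, losses = character(0)))
  }
  if (k == "chrom_loss") {
    r <- which(vapply(tg$records, function(x)
      x$name == ev$chrom &&
        (is.null(ev$haplotype) || x$haplotype == ev$haplotype),
      logical(1)))
    if (length(r) != 1) stop("chrom_loss: need exactly one matching record")
    lost <- sites_in_tokens(tg$records[[r]]$tokens)
    tg$records[[r]] <- NULL
    return(list(tg = tg, junctions = NULL, losses = lost))
  }
  if (k == "loh_conversion") {
    dir <- ev$params$direction %||% "to_wildtype"
    if (dir == "to_wildtype") {
      lost <- character(0)
      for (s in ev$sites) {
        p <- find_lox(tg, s)
        toks <- tg$records[[p[1]]]$tokens
        tok <- toks[[p[2]]]
        if (tok$lend[["site"]] != tok$rend[["site"]] ||
            tok$lend[["side"]] != "u")
          stop("loh_conversion across a rearranged lox token at ", s)
        toks[[p[2]]] <- list(type = "seq", seq = "")
        tg$records[[p[1]]]$tokens <- toks
        lost <- c(lost, s)
      }
      return(list(tg = tg, junctions = NULL, losses = lost))
    }
    stop("loh_conversion direction 'to_lox' is applied by make_diploid()")
  }
  stop("unhandled event kind: ", k)
}

#' Apply Cre-mediated structural-variant events to a genome
#'
#' Events are applied sequentially in list order; each event re-resolves its
#' sites against the current genome, so composed simulations remain
#' consistent. The returned [event log][expected_junctions] records, per
#' event, the junction end-pairs it creates and the loci it destroys, plus
#' the full set of junctions realised in the final genome (the acceptance
#' oracle for junction detection).
#'
#' @param genome a `genome_model` carrying the motifs in `sites`.
#' @param sites the genome's `lox_site_table`.
#' @param events list of [sv_event()]s.
#' @param lox_seq motif sequence (default taken from `sites`).
#' @return `list(genome =, sites =, log =)`: the rearranged genome, its
#'   post-event site table (junction loxes keep the label of their left
#'   parental locus; duplicated loci are suffixed to stay unique), and the
#'   `event_log`.
#' @export
apply_events <- function(genome, sites, events, lox_seq = NULL) {
  tg <- tokenize_genome(genome, sites, lox_seq)
  log <- new_event_log()
  for (ev in events) {
    if (!inherits(ev, "sv_event")) stop("events must be sv_event objects")
    res <- apply_one_event(tg, ev)
    tg <- res$tg
    log <- log_event(log, ev, res$junctions, res$losses)
  }
  log$final_junctions <- token_junctions(tg)
  out <- detokenize_genome(tg)
  if (!is.null(out$sites)) attr(out$sites, "lox_seq") <- tg$lox_seq
  lox_log("apply_events: ", length(events), " event(s), ",
          sum(log$final_junctions$class == "novel"),
          " novel junction(s) in final genome")
  list(genome = out$genome, sites = out$sites, log = log)
}

# ---- diploids -------------------------------------------------------------

#' Combine two haplotypes into a diploid and apply LOH/aneuploidy events
#'
#' `hapA` is the lox-bearing haplotype described by `sites`; `hapB` is its
#' homolog (typically lox-free wild type sharing the chromosome names).
#' `loh_conversion` with direction `"to_wildtype"` overwrites the lox allele
#' with the homologous wild-type interval — since the haplotypes differ only
#' by the spliced-in motifs, this removes the motif and leaves both flanks
#' intact, which is exactly the signature read out by the LOH caller.
#' Direction `"to_lox"` copies the motif onto the homolog instead.
#'
#' @param hapA,hapB `genome_model`s sharing chromosome names.
#' @param sites `lox_site_table` of `hapA`.
#' @param events list of [sv_event()]s (`loh_conversion`, `chrom_gain`,
#'   `chrom_loss`; Cre-type events are also accepted and act on the lox
#'   haplotype).
#' @param hap_labels labels for the two haplotypes.
#' @return `list(genome =, sites =, log =)`; `sites` carries a `haplotype`
#'   column.
#' @export
make_diploid <- function(hapA, hapB, sites, events = list(),
                         hap_labels = c("A", "B")) {
  if (!setequal(hapA$records$name, hapB$records$name))
    stop("haplotypes must share chromosome names")
  gA <- hapA; gA$records$haplotype <- hap_labels[1]
  gB <- hapB; gB$records$haplotype <- hap_labels[2]
  dip <- genome_model(c(gA$records$name, gB$records$name),
                      c(unlist(gA$seq), unlist(gB$seq)),
                      haplotype = c(gA$records$haplotype,
                                    gB$records$haplotype),
                      topology = c(gA$records$topology,
                                   gB$records$topology))
  # homology check: lox flanks must match between haplotypes
  lox_seq <- attr(sites, "lox_seq") %||% LOXPSYM_SEQ
  for (i in seq_len(min(nrow(sites), 5L))) {
    rA <- record_index(dip, sites$chrom[i], hap_labels[1])
    rB <- record_index(dip, sites$chrom[i], hap_labels[2])
    p <- sites$position[i]
    on_chr <- sites[sites$chrom == sites$chrom[i] & sites$position < p, ,
                    drop = FALSE]
    pB <- p - 34L * sum(on_chr$copies) # wild-type coordinate of the locus
    w <- min(50L, p - 1L)
    if (w > 5 && substr(dip$seq[[rA]], p - w, p - 1L) !=
        substr(dip$seq[[rB]], pB - w, pB - 1L))
      stop("haplotypes are not homologous around site ", sites$site_id[i])
  }
  # to_lox conversions are insertions on hapB; do them before tokenising
  evs <- events
  drop <- logical(length(evs))
  for (k in seq_along(evs)) {
    ev <- evs[[k]]
    if (ev$kind == "loh_conversion" &&
        identical(ev$params$direction, "to_lox")) {
      s <- sites[match(ev$sites, sites$site_id), , drop = FALSE]
      if (anyNA(s$position)) stop("unknown site in loh_conversion")
      for (i in seq_len(nrow(s))) {
        rB <- record_index(dip, s$chrom[i], hap_labels[2])
        prior <- sites[sites$chrom == s$chrom[i] &
                         sites$position < s$position[i], , drop = FALSE]
        pB <- s$position[i] - 34L * sum(prior$copies)
        dip$seq[[rB]] <- paste0(substr(dip$seq[[rB]], 1L, pB - 1L),
                                strrep(lox_seq, s$copies[i]),
                                substr(dip$seq[[rB]], pB,
                                       nchar(dip$seq[[rB]])))
      }
      drop[k] <- TRUE
    }
  }
  evs <- evs[!drop]
  res <- apply_events(dip, sites, evs, lox_seq = lox_seq)
  res
}

# ---- read simulation ------------------------------------------------------

#' Long-read simulation parameters
#'
#' Lognormal read lengths and i.i.d. per-base errors, emulating
#' nanopore-style long reads. `exp(meanlog)` is the median read length.
#'
#' @param coverage fold coverage of the total genome.
#' @param meanlog,sdlog lognormal length parameters.
#' @param min_len minimum read length (bp).
#' @param sub_rate,ins_rate,del_rate per-base error fractions (sum < 0.5).
#' @param seed RNG seed.
#' @return a `read_sim_params` list.
#' @export
read_sim_params <- function(coverage = 20, meanlog = log(8000), sdlog = 0.5,
                            min_len = 500L, sub_rate = 0.03,
                            ins_rate = 0.01, del_rate = 0.01, seed = 1L) {
  stopifnot(coverage > 0, sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate < 0.5, min_len > 0)
  structure(list(coverage = coverage, meanlog = meanlog, sdlog = sdlog,
                 min_len = as.integer(min_len), sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate long reads from a genome
#'
#' Read start positions are uniform over the genome (chromosomes weighted by
#' length); reads on circular chromosomes wrap around the origin; reads on
#' linear chromosomes truncate at the ends. Strand is uniform. Reads are
#' emitted until the error-free base total reaches `coverage` times the
#' genome size, so realised coverage is within one read of the target. The
#' truth map records each read's source record, interval and strand.
#'
#' @param genome a `genome_model`.
#' @param params a [read_sim_params()].
#' @return a `read_set`: `list(reads = named character vector,
#'   truth = data.frame, params)`.
#' @export
simulate_reads <- function(genome, params) {
  stopifnot(inherits(params, "read_sim_params"))
  lens <- vapply(genome$seq, nchar, numeric(1))
  target <- params$coverage * sum(lens)
  with_seed(params$seed, {
    n_guess <- ceiling(1.3 * target / exp(params$meanlog +
                                            params$sdlog^2 / 2)) + 10L
    recs <- integer(0); starts <- integer(0); rlens <- integer(0)
    total <- 0
    while (total < target) {
      L <- pmax(params$min_len,
                floor(stats::rlnorm(n_guess, params$meanlog, params$sdlog)))
      r <- sample.int(length(lens), n_guess, replace = TRUE,
                      prob = lens / sum(lens))
      s <- floor(stats::runif(n_guess) * lens[r]) + 1L
      circ <- genome$records$topology[r] == "circular"
      L <- as.integer(pmin(L, lens[r]))
      eff <- ifelse(circ, L, pmin(L, lens[r] - s + 1L))
      keep <- cumsum(eff) + total <= target + max(eff)
      keep[which(!keep)[-1]] <- FALSE # stop after first overshoot read
      recs <- c(recs, r[keep]); starts <- c(starts, s[keep])
      rlens <- c(rlens, as.integer(eff[keep]))
      total <- total + sum(eff[keep])
    }
    n <- length(recs)
    seqs <- character(n)
    for (rr in unique(recs)) {
      w <- which(recs == rr)
      chr <- genome$seq[[rr]]
      if (genome$records$topology[rr] == "circular") {
        chr2 <- paste0(chr, substr(chr, 1L, max(rlens[w])))
        seqs[w] <- substring(chr2, starts[w], starts[w] + rlens[w] - 1L)
      } else {
        seqs[w] <- substring(chr, starts[w], starts[w] + rlens[w] - 1L)
      }
    }
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    seqs[strand == "-"] <- dna_revcomp(seqs[strand == "-"])
    if (params$sub_rate + params$ins_rate + params$del_rate > 0)
      seqs <- as.character(cpp_mutate_reads(seqs, params$sub_rate,
                                            params$ins_rate,
                                            params$del_rate))
    ids <- sprintf("read%06d", seq_len(n))
    truth <- data.frame(read_id = ids,
                        chrom = genome$records$name[recs],
                        haplotype = genome$records$haplotype[recs],
                        start = starts - 1L, # 0-based half-open
                        end = starts - 1L + rlens,
                        strand = strand, stringsAsFactors = FALSE)
    lox_log("simulate_reads: ", n, " read(s), ", round(total / sum(lens), 2),
            "x coverage")
    structure(list(reads = stats::setNames(seqs, ids), truth = truth,
                   params = params), class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", length(x$reads), "reads,",
      format(sum(nchar(x$reads)), big.mark = ","), "bases\n")
  invisible(x)
}

#' Write a read set (or named character vector) as FASTQ
#' @param reads a `read_set` or named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  con <- file(path, open = "wb")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con,
             sep = "\n")
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#' @param path FASTQ path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(ss),
                  vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1))
}
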