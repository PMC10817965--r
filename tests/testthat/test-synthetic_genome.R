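# simulator: genomes, lox insertion, SV events, diploids, reads

test_that("toy genomes are reproducible with the requested composition", {
  g1 <- make_toy_genome(2, c(100000, 50000), gc = 0.38, seed = 7)
  g2 <- make_toy_genome(2, c(100000, 50000), gc = 0.38, seed = 7)
  expect_identical(g1$seq, g2$seq)
  expect_equal(unname(chrom_lengths(g1)), c(100000L, 50000L))
  big <- make_toy_genome(1, 1000000, gc = 0.38, seed = 3)
  gcobs <- sum(strsplit(big$seq[[1]], "")[[1]] %in% c("G", "C")) / 1e6
  expect_gt(gcobs, 0.36)
  expect_lt(gcobs, 0.40)
})

test_that("insert_lox splices motifs and shifts downstream coordinates", {
  g <- make_toy_genome(1, 1000, seed = 2)
  one <- insert_lox(g, data.frame(chrom = "chrI", position = 500))
  expect_equal(nchar(one$genome$seq[[1]]), 1034L)
  g2 <- make_toy_genome(1, 2000, seed = 2)
  two <- insert_lox(g2, data.frame(chrom = "chrI", position = c(200, 600)),
                    min_gap = 100)
  expect_equal(two$sites$position, c(200L, 634L)) # second shifted by 34
  expect_equal(substr(two$genome$seq[[1]], 634, 667), LOXPSYM_SEQ)
  expect_error(insert_lox(g, data.frame(chrom = "chrI", position = 5000)),
               "outside")
  # random layout satisfies the per-chromosome constraint
  g3 <- make_toy_genome(4, rep(150000, 4), seed = 9)
  rnd <- insert_lox(g3, list(n_loci = 12, min_per_chrom = 2, seed = 5))
  expect_equal(nrow(rnd$sites), 12L)
  expect_true(all(table(rnd$sites$chrom) >= 2))
})

test_that("deletion removes interval + 34 bp and leaves one fused lox", {
  tg <- tiny_lox_genome(lens = 100000, n_per = 2)
  p <- tg$sites$position
  res <- apply_events(tg$genome, tg$sites,
                      list(sv_event("deletion", sites = c("I-1", "I-2"))))
  # removed: the inter-motif interval plus one of the two lox copies,
  # i.e. exactly p2 - p1 in post-insertion coordinates
  expect_equal(nchar(res$genome$seq[[1]]),
               nchar(tg$genome$seq[[1]]) - (p[2] - p[1]))
  # exactly one motif remains
  n_motifs <- length(gregexpr(LOXPSYM_SEQ, res$genome$seq[[1]],
                              fixed = TRUE)[[1]])
  expect_equal(n_motifs, 1L)
  ej <- expected_junctions(res$log)
  expect_equal(ej$key, "I-1:u|I-2:d")
  # the fused junction sequence joins U_1 to D_2
  fl <- extract_flanks(tg$genome, tg$sites, 200)
  at <- regexpr(LOXPSYM_SEQ, res$genome$seq[[1]], fixed = TRUE)[[1]]
  expect_equal(substr(res$genome$seq[[1]], at - 200, at - 1), fl$up_seq[1])
  expect_equal(substr(res$genome$seq[[1]], at + 34, at + 233),
               fl$down_seq[2])
})

test_that("inversion conserves length and reverse-complements the interval", {
  tg <- tiny_lox_genome(lens = 80000, n_per = 2)
  p <- tg$sites$position
  res <- apply_events(tg$genome, tg$sites,
                      list(sv_event("inversion", sites = c("I-1", "I-2"))))
  expect_equal(nchar(res$genome$seq[[1]]), nchar(tg$genome$seq[[1]]))
  inner_old <- substr(tg$genome$seq[[1]], p[1] + 34, p[2] - 1)
  inner_new <- substr(res$genome$seq[[1]], p[1] + 34, p[2] - 1)
  expect_equal(inner_new, dna_revcomp(inner_old))
  expect_setequal(expected_junctions(res$log)$key,
                  c("I-1:u|I-2:u", "I-1:d|I-2:d"))
})

test_that("reciprocal translocation conserves total length", {
  tg <- tiny_lox_genome(lens = c(90000, 70000), n_per = c(2, 2))
  res <- apply_events(tg$genome, tg$sites,
                      list(sv_event("translocation_reciprocal",
                                    sites = c("I-1", "II-2"))))
  expect_equal(sum(chrom_lengths(res$genome)),
               sum(chrom_lengths(tg$genome)))
  expect_setequal(expected_junctions(res$log)$key,
                  c("I-1:u|II-2:d", "I-1:d|II-2:u"))
  # same-chromosome translocation is rejected
  expect_error(apply_events(tg$genome, tg$sites,
                            list(sv_event("translocation_reciprocal",
                                          sites = c("I-1", "I-2")))),
               "different chromosomes")
})

test_that("duplication adds interval + 34 and creates the tandem junction", {
  tg <- tiny_lox_genome(lens = 80000, n_per = 2)
  p <- tg$sites$position
  res <- apply_events(tg$genome, tg$sites,
                      list(sv_event("duplication", sites = c("I-1", "I-2"))))
  expect_equal(nchar(res$genome$seq[[1]]),
               nchar(tg$genome$seq[[1]]) + (p[2] - p[1]))
  expect_equal(expected_junctions(res$log)$key, "I-1:d|I-2:u")
})

test_that("circularization keeps the inner segment as a circle", {
  tg <- tiny_lox_genome(lens = 100000, n_per = 3)
  res <- apply_events(tg$genome, tg$sites,
                      list(sv_event("circularization",
                                    sites = c("I-1", "I-3"))))
  expect_equal(res$genome$records$topology[1], "circular")
  expect_equal(expected_junctions(res$log)$key, "I-1:d|I-3:u")
  expect_true("I-3" %in% res$log$losses)
  expect_false("I-2" %in% res$log$losses) # interior locus survives
})

test_that("events referencing destroyed sites are rejected as conflicts", {
  tg <- tiny_lox_genome(lens = 120000, n_per = 4)
  evs <- list(sv_event("deletion", sites = c("I-1", "I-3")),
              sv_event("inversion", sites = c("I-2", "I-4"))) # I-2 deleted
  expect_error(apply_events(tg$genome, tg$sites, evs), "I-2")
})

test_that("every novel adjacency in the emitted genome is in the log", {
  # independent oracle: locate every motif in the final sequence and read
  # off its flanks from the parental flank library by exact string match
  tg <- tiny_lox_genome(lens = c(150000, 120000), n_per = c(3, 3))
  evs <- list(sv_event("deletion", sites = c("I-1", "I-2")),
              sv_event("inversion", sites = c("II-1", "II-2")),
              sv_event("translocation_reciprocal",
                       sites = c("I-3", "II-3")))
  res <- apply_events(tg$genome, tg$sites, evs)
  fl <- extract_flanks(tg$genome, tg$sites, 150, min_flank = 50)
  left_of <- c(setNames(paste0(fl$site_id, ":u"), fl$up_seq),
               setNames(paste0(fl$site_id, ":d"),
                        dna_revcomp(fl$down_seq)))
  right_of <- c(setNames(paste0(fl$site_id, ":d"), fl$down_seq),
                setNames(paste0(fl$site_id, ":u"),
                         dna_revcomp(fl$up_seq)))
  seen <- character(0)
  for (r in seq_along(res$genome$seq)) {
    s <- res$genome$seq[[r]]
    for (at in gregexpr(LOXPSYM_SEQ, s, fixed = TRUE)[[1]]) {
      lf <- substr(s, at - 150, at - 1)
      rf <- substr(s, at + 34, at + 183)
      ends <- sort(c(left_of[[lf]], right_of[[rf]]))
      seen <- c(seen, paste(ends, collapse = "|"))
    }
  }
  fj <- res$log$final_junctions
  expect_setequal(unique(seen), fj$key)
  novel_truth <- expected_junctions(res$log)$key
  expect_true(all(novel_truth %in% seen))
})

test_that("diploid LOH removes the motif while aneuploidy edits records", {
  tg <- tiny_lox_genome(lens = c(100000, 80000), n_per = c(2, 2))
  dip <- make_diploid(tg$genome, tg$base, tg$sites,
                      list(sv_event("loh_conversion", sites = "I-1"),
                           sv_event("chrom_gain", chrom = "chrII",
                                    haplotype = "B"),
                           sv_event("chrom_loss", chrom = "chrI",
                                    haplotype = "B")))
  expect_true("I-1" %in% dip$log$losses)
  recs <- dip$genome$records
  expect_equal(sum(recs$name == "chrII"), 3L)
  expect_equal(sum(recs$name == "chrI"), 1L)
  # the LOH locus is motif-free on haplotype A but flanks are intact
  hapA_I <- dip$genome$seq[[which(recs$name == "chrI")[1]]]
  expect_equal(nchar(hapA_I), 100000L + 34L) # one of two motifs removed
  # to_lox copies the motif onto the homolog
  dip2 <- make_diploid(tg$genome, tg$base, tg$sites,
                       list(sv_event("loh_conversion", sites = "II-1",
                                     direction = "to_lox")))
  hapB_II <- dip2$genome$seq[[with(dip2$genome$records,
                                   which(name == "chrII" &
                                           haplotype == "B"))]]
  expect_equal(nchar(hapB_II), 80000L + 34L)
})

test_that("simulated reads honour coverage, lengths, strand and errors", {
  g <- make_toy_genome(1, 300000, seed = 13)
  p0 <- read_sim_params(coverage = 6, sub_rate = 0, ins_rate = 0,
                        del_rate = 0, seed = 4)
  rs <- simulate_reads(g, p0)
  expect_lt(abs(sum(nchar(rs$reads)) / 300000 - 6), 0.05 * 6)
  # zero-error reads are exact substrings of the genome or its revcomp
  chr <- g$seq[[1]]
  for (i in sample(length(rs$reads), 25)) {
    rd <- rs$reads[[i]]
    tr <- rs$truth[i, ]
    src <- substr(chr, tr$start + 1, tr$end)
    expect_identical(rd, if (tr$strand == "+") src else dna_revcomp(src))
  }
  # seed determinism
  rs2 <- simulate_reads(g, p0)
  expect_identical(rs$reads, rs2$reads)
  # substitution rate recovered empirically
  ps <- read_sim_params(coverage = 4, sub_rate = 0.05, ins_rate = 0,
                        del_rate = 0, seed = 9)
  rse <- simulate_reads(g, ps)
  mm <- 0; tot <- 0
  for (i in seq_along(rse$reads)) {
    tr <- rse$truth[i, ]
    src <- substr(chr, tr$start + 1, tr$end)
    if (tr$strand == "-") src <- dna_revcomp(src)
    a <- strsplit(rse$reads[[i]], "")[[1]]; b <- strsplit(src, "")[[1]]
    mm <- mm + sum(a != b); tot <- tot + length(a)
  }
  expect_gt(mm / tot, 0.045)
  expect_lt(mm / tot, 0.055)
  # lognormal length median
  pl <- read_sim_params(coverage = 10, meanlog = 9.2, sdlog = 0.5,
                        sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 2)
  rsl <- simulate_reads(g, pl)
  expect_lt(abs(median(nchar(rsl$reads)) - exp(9.2)) / exp(9.2), 0.10)
})

test_that("reads wrap around circular chromosomes", {
  g <- make_toy_genome(1, 50000, seed = 17)
  g$records$topology <- "circular"
  rs <- simulate_reads(g, read_sim_params(coverage = 5, sub_rate = 0,
                                          ins_rate = 0, del_rate = 0,
                                          meanlog = log(8000), seed = 3))
  doubled <- paste0(g$seq[[1]], g$seq[[1]])
  wrapped <- which(rs$truth$end > 50000)
  expect_gt(length(wrapped), 0)
  for (i in wrapped) {
    tr <- rs$truth[i, ]
    src <- substr(doubled, tr$start + 1, tr$end)
    if (tr$strand == "-") src <- dna_revcomp(src)
    expect_identical(rs$reads[[i]], src)
  }
})
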