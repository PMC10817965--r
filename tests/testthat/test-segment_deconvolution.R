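# segment maps, marker partitioning, junction observation, reconstruction

test_that("segment map tiles the chromosome around its motifs", {
  tg <- tiny_lox_genome(lens = 70000, n_per = 3, seed = 81)
  sm <- segment_map(tg$genome, tg$sites, "chrI")
  expect_equal(nrow(sm), 4L)
  rebuilt <- paste(sm$seq, collapse = LOXPSYM_SEQ)
  expect_identical(rebuilt, tg$genome$seq[[1]])
})

test_that("marker partitioning follows the majority rule", {
  set.seed(9)
  syn <- vapply(1:3, function(i) loxscan:::cpp_random_dna(28, 0.5), character(1))
  wt <- vapply(1:3, function(i) loxscan:::cpp_random_dna(28, 0.5), character(1))
  mk <- marker_table(rep(paste0("m", 1:3), 2),
                     rep(c("synthetic", "wildtype"), each = 3),
                     c(syn, wt), rep(1:3, 2))
  pad <- function(...) paste0(loxscan:::cpp_random_dna(300, 0.4), ...,
                              loxscan:::cpp_random_dna(300, 0.4))
  reads <- c(s1 = pad(syn[1], loxscan:::cpp_random_dna(50, .4), syn[2]),
             t1 = pad(syn[1], loxscan:::cpp_random_dna(50, .4), wt[2]),
             n1 = pad(loxscan:::cpp_random_dna(60, .4)),
             w1 = pad(dna_revcomp(wt[3]))) # reverse strand counts too
  pt <- partition_reads_by_markers(reads, mk, max_edits = 2)
  expect_equal(pt$synthetic, "s1")
  expect_equal(pt$wildtype, "w1")
  expect_setequal(pt$unassigned, c("t1", "n1"))
  # at 5% error, assignment is still near-perfect and never flips
  tg <- tiny_lox_genome(lens = 60000, n_per = 3, seed = 82)
  sm <- segment_map(tg$genome, tg$sites, "chrI")
  mks <- marker_table(paste0("t", 1:4),
                      rep(c("synthetic", "wildtype"), 2),
                      c(substr(sm$seq[2], 100, 127),
                        loxscan:::cpp_random_dna(28, 0.5),
                        substr(sm$seq[3], 100, 127),
                        loxscan:::cpp_random_dna(28, 0.5)),
                      c(2, 2, 3, 3))
  rs <- simulate_reads(tg$genome,
                       read_sim_params(coverage = 4, meanlog = log(9000),
                                       seed = 83))
  pt2 <- partition_reads_by_markers(rs, mks, max_edits = 2)
  # reads overlapping a marker position should mostly be synthetic
  expect_equal(length(pt2$wildtype), 0L) # nothing matches the decoys
  expect_gt(length(pt2$synthetic), 0L)
})

test_that("observed junctions mirror the parental and inverted layouts", {
  tg <- tiny_lox_genome(lens = 90000, n_per = 3, seed = 85)
  cfg <- pipeline_config(flank_len = 500, min_score_margin = 10)
  rs <- simulate_reads(tg$genome,
                       read_sim_params(coverage = 6, sub_rate = 0,
                                       ins_rate = 0, del_rate = 0,
                                       meanlog = log(6000), seed = 86))
  ob <- observe_junctions(rs, tg$genome, tg$sites, "chrI", cfg)
  expect_setequal(paste(ob$observations$seg_a, ob$observations$end_a,
                        ob$observations$seg_b, ob$observations$end_b),
                  c("1 tail 2 head", "2 tail 3 head", "3 tail 4 head"))
  # inversion between sites 1 and 2 flips segment 2's junctions
  inv <- apply_events(tg$genome, tg$sites,
                      list(sv_event("inversion", sites = c("I-1", "I-2"))))
  rs2 <- simulate_reads(inv$genome,
                        read_sim_params(coverage = 6, sub_rate = 0,
                                        ins_rate = 0, del_rate = 0,
                                        meanlog = log(6000), seed = 87))
  ob2 <- observe_junctions(rs2, tg$genome, tg$sites, "chrI", cfg)
  expect_setequal(paste(ob2$observations$seg_a, ob2$observations$end_a,
                        ob2$observations$seg_b, ob2$observations$end_b),
                  c("1 tail 2 tail", "2 head 3 head", "3 tail 4 head"))
  # a junction fused to foreign sequence lands in the unassigned report
  chr <- tg$genome$seq[[1]]
  p <- tg$sites$position[1]
  chim <- paste0(substr(chr, p - 800, p + 33), loxscan:::cpp_random_dna(800, 0.4))
  ob3 <- observe_junctions(c(x1 = chim), tg$genome, tg$sites, "chrI", cfg)
  expect_equal(nrow(ob3$observations), 0L)
  expect_equal(nrow(ob3$unassigned), 1L)
  expect_equal(ob3$unassigned$left_matched, "I-1")
})

test_that("reconstruction inverts junctions_of_arrangement exactly", {
  cases <- list(
    list(seg = c(1, 2, 3), ori = c("+", "+", "+"), top = "linear"),
    list(seg = c(1, 2, 3), ori = c("+", "-", "+"), top = "linear"),
    list(seg = c(2, 1, 3, 4), ori = c("-", "+", "-", "+"),
         top = "linear"),
    list(seg = c(1, 2, 3), ori = c("+", "+", "+"), top = "circular"),
    list(seg = c(1, 3, 2, 4), ori = c("+", "-", "-", "+"),
         top = "circular"))
  for (cs in cases) {
    obs <- junctions_of_arrangement(cs$seg, cs$ori, cs$top)
    res <- reconstruct(obs, n_segments = max(cs$seg), min_support = 1)
    expect_equal(res$topology, cs$top)
    expect_false(res$ambiguous)
    expect_equal(canon_of(res),
                 loxscan:::canon_arrangement(cs$seg, cs$ori, cs$top))
  }
})

test_that("copy-aware cases: deletions drop segments, duplications repeat", {
  # deletion of segment 2 from [1,2,3]
  obs <- junctions_of_arrangement(c(1, 3), c("+", "+"))
  res <- reconstruct(obs, copy_numbers = c("1" = 1, "2" = 0, "3" = 1),
                     n_segments = 3, min_support = 1)
  expect_equal(res$arrangement$segment_id, c(1, 3))
  # tandem duplication [1,2,2,3]
  obs2 <- junctions_of_arrangement(c(1, 2, 2, 3), rep("+", 4))
  res2 <- reconstruct(obs2, copy_numbers = c("1" = 1, "2" = 2, "3" = 1),
                      min_support = 1)
  keys <- vapply(res2$alternatives, function(a)
    loxscan:::canon_arrangement(a$segment_id, a$orientation,
                                res2$topology), character(1))
  expect_true(loxscan:::canon_arrangement(c(1, 2, 2, 3), rep("+", 4),
                                          "linear") %in% keys)
})

test_that("inconsistent junction sets raise informative errors", {
  # three junctions all grabbing segment 2's head exceeds its copy number
  obs <- data.frame(seg_a = c(1, 3, 4), end_a = rep("tail", 3),
                    seg_b = c(2, 2, 2), end_b = rep("head", 3),
                    support = 5L)
  expect_error(reconstruct(obs, n_segments = 4, min_support = 1),
               "exceed copy number")
  # support filtering drops weak junctions
  obs2 <- junctions_of_arrangement(c(1, 2), c("+", "+"))
  obs2$support <- 1L
  expect_error(reconstruct(obs2, n_segments = 2, min_support = 2),
               "no arrangement|free")
})

test_that("reconstruction matches the exhaustive oracle on small cases", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(2:4, 1)
    seg <- sample(n)
    ori <- sample(c("+", "-"), n, replace = TRUE)
    obs <- junctions_of_arrangement(seg, ori)
    res <- reconstruct(obs, n_segments = n, min_support = 1,
                       max_alternatives = 64)
    got <- sort(vapply(res$alternatives, function(a)
      loxscan:::canon_arrangement(a$segment_id, a$orientation,
                                  res$topology), character(1)))
    want <- all_consistent_arrangements(
      obs, setNames(rep(1L, n), as.character(seq_len(n))))
    expect_equal(got, want)
  }
})

test_that("random signed permutations round-trip up to global flip", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    seg <- sample(n)
    ori <- sample(c("+", "-"), n, replace = TRUE)
    obs <- junctions_of_arrangement(seg, ori)
    res <- reconstruct(obs, n_segments = n, min_support = 1)
    expect_false(res$ambiguous)
    expect_equal(canon_of(res),
                 loxscan:::canon_arrangement(seg, ori, "linear"))
  }
})
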