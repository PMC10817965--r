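# rearrangement_stats: RR / ARR / RW, intra vs inter classification,
# outliers, regressions, group tests and network export.
#
# Definitions (per locus i, pair (i, j)):
#   RR_i    = Nre_i / (2 * Nnorm_i + Nre_i)            (rearrangement rate)
#   RW_ij   = Nre_ij / sqrt(Nall_i * Nall_j)           (rearrangement weight)
#   Nall_i  = 2 * Nnorm_i + Nre_i
# ARR normalises a class-restricted RR for partner opportunity (see
# compute_arr). All three are invariant under uniform scaling of the
# counts, the property that makes them comparable across sequencing depths.

#' Per-locus rearrangement rate
#'
#' @param counts a `counts_table`.
#' @return data frame `site_id`, `rr` (`NA` where `Nall = 0`).
#' @export
compute_rr <- function(counts) {
  ps <- counts$per_site
  rr <- ifelse(ps$n_all > 0, ps$n_re / ps$n_all, NA_real_)
  data.frame(site_id = ps$site_id, rr = rr, stringsAsFactors = FALSE)
}

# class label of each pair given the site table
pair_class <- function(site_a, site_b, sites) {
  ca <- sites$chrom[match(site_a, sites$site_id)]
  cb <- sites$chrom[match(site_b, sites$site_id)]
  ifelse(ca == cb, "intra", "inter")
}

#' Per-locus average rearrangement rate (ARR)
#'
#' The class-restricted rate `Nre_{i,class} / Nall_i` divided by a
#' normaliser. With `normalization = "partners"` (default) the normaliser
#' is the number of possible partner loci of that class for locus i, making
#' intra- and inter-chromosomal activity comparable per partner
#' opportunity; with `"total_rearranged"` it is the total number of loci
#' with any rearranged read (a global constant).
#'
#' @param counts a `counts_table`.
#' @param sites the `lox_site_table` (for chromosome assignment).
#' @param class `"intra"` or `"inter"`.
#' @param normalization `"partners"` or `"total_rearranged"`.
#' @return data frame `site_id`, `arr` (`NA` where the normaliser is 0 or
#'   `Nall = 0`).
#' @export
compute_arr <- function(counts, sites, class = c("intra", "inter"),
                        normalization = c("partners", "total_rearranged")) {
  class <- match.arg(class)
  normalization <- match.arg(normalization)
  ps <- counts$per_site
  pp <- counts$per_pair
  cls <- if (nrow(pp)) pair_class(pp$site_a, pp$site_b, sites) else
    character(0)
  nre_class <- stats::setNames(numeric(nrow(ps)), ps$site_id)
  keep <- which(cls == class)
  for (i in keep) {
    nre_class[pp$site_a[i]] <- nre_class[pp$site_a[i]] + pp$n_re[i]
    if (pp$site_b[i] != pp$site_a[i])
      nre_class[pp$site_b[i]] <- nre_class[pp$site_b[i]] + pp$n_re[i]
  }
  chrom <- sites$chrom[match(ps$site_id, sites$site_id)]
  n_per_chrom <- table(sites$chrom)
  partners <- if (class == "intra")
    as.numeric(n_per_chrom[chrom]) - 1 else
      nrow(sites) - as.numeric(n_per_chrom[chrom])
  denom <- switch(normalization,
                  partners = partners,
                  total_rearranged = rep(sum(ps$n_re > 0), nrow(ps)))
  arr <- ifelse(ps$n_all > 0 & denom > 0,
                (nre_class / ps$n_all) / denom, NA_real_)
  data.frame(site_id = ps$site_id, arr = as.numeric(arr),
             stringsAsFactors = FALSE)
}

#' Rearrangement-weight matrix
#'
#' `RW_ij = Nre_ij / sqrt(Nall_i * Nall_j)`, 0 when either `Nall` is 0;
#' symmetric with zero diagonal (unless self pairs were counted).
#'
#' @param counts a `counts_table`.
#' @return symmetric numeric matrix (class `rw_matrix`), loci as dimnames.
#' @export
compute_rw <- function(counts) {
  ps <- counts$per_site
  nre <- pair_count_matrix(counts)
  nall <- stats::setNames(ps$n_all, ps$site_id)
  sc <- sqrt(outer(nall, nall))
  rw <- ifelse(sc > 0, nre / sc, 0)
  class(rw) <- c("rw_matrix", class(rw))
  rw
}

#' Long-format pair table for an RW matrix
#'
#' One row per unordered locus pair with RW, intra/inter class, genomic
#' distance (intra pairs, post-insertion coordinates) and same-arm flag
#' when centromeres are supplied.
#'
#' @param rw an `rw_matrix`.
#' @param sites the `lox_site_table`.
#' @param centromeres optional `centromere_table`.
#' @return data frame `site_a`, `site_b`, `rw`, `class`, `distance`,
#'   `same_arm`.
#' @export
rw_long <- function(rw, sites, centromeres = NULL) {
  loci <- rownames(rw)
  pr <- utils::combn(length(loci), 2)
  a <- loci[pr[1, ]]; b <- loci[pr[2, ]]
  ia <- match(a, sites$site_id); ib <- match(b, sites$site_id)
  cls <- ifelse(sites$chrom[ia] == sites$chrom[ib], "intra", "inter")
  d <- ifelse(cls == "intra",
              abs(sites$position[ia] - sites$position[ib]), NA_real_)
  same_arm <- rep(NA, length(a))
  if (!is.null(centromeres)) {
    ci <- match(sites$chrom[ia], centromeres$chrom)
    arm_a <- ifelse(sites$position[ia] < centromeres$cen_start[ci], "L",
                    ifelse(sites$position[ia] > centromeres$cen_end[ci],
                           "R", "C"))
    cj <- match(sites$chrom[ib], centromeres$chrom)
    arm_b <- ifelse(sites$position[ib] < centromeres$cen_start[cj], "L",
                    ifelse(sites$position[ib] > centromeres$cen_end[cj],
                           "R", "C"))
    same_arm <- cls == "intra" & arm_a == arm_b & arm_a != "C"
  }
  data.frame(site_a = a, site_b = b, rw = rw[cbind(pr[1, ], pr[2, ])],
             class = cls, distance = d, same_arm = same_arm,
             stringsAsFactors = FALSE)
}

#' Upper-tail Tukey outliers
#'
#' Values above `Q3 + 1.5 * IQR` (quartiles by linear interpolation,
#' `quantile` type 7). Particularly active loci show up here.
#'
#' @param values named numeric vector (NAs dropped).
#' @param k fence multiplier.
#' @return the outlying elements of `values`.
#' @export
find_outliers <- function(values, k = 1.5) {
  v <- values[!is.na(values)]
  if (length(v) < 5) stop("need >= 5 values for outlier detection")
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2] + k * (q[2] - q[1])
  v[v > fence]
}

#' Regression of RW on inverse genomic distance (same-arm pairs)
#'
#' Ordinary least squares of `RW_ij` on `1 / d_ij` over intra-chromosomal
#' pairs whose two loci lie strictly on the same chromosome arm
#' (centromere-spanning pairs are excluded).
#'
#' @param rw an `rw_matrix`.
#' @param sites the `lox_site_table`.
#' @param centromeres a `centromere_table`.
#' @return a `regression_result`: slope, intercept, r_squared, p_value,
#'   n_pairs.
#' @export
rw_distance_regression <- function(rw, sites, centromeres) {
  long <- rw_long(rw, sites, centromeres)
  use <- long$class == "intra" & long$same_arm %in% TRUE & long$distance > 0
  if (sum(use) < 3)
    stop("need >= 3 same-arm pairs with nonzero distance (have ",
         sum(use), ")")
  df <- long[use, ]
  fit <- stats::lm(rw ~ I(1 / distance), data = df)
  sm <- suppressWarnings(summary(fit)) # exact fits warn harmlessly
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = if (nrow(df) > 2 && sm$sigma > 0)
                   unname(sm$coefficients[2, 4]) else NA_real_,
                 n_pairs = nrow(df)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "regression: slope %.4g, intercept %.4g, R^2 %.4f, p %.3g (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n_pairs))
  invisible(x)
}

#' Assemble per-locus site rates
#'
#' Joins RR, intra/inter ARR, chromosome/arm assignment and an
#' open-chromatin flag (a locus is open when its motif start overlaps any
#' interval of `open_regions`).
#'
#' @param counts a `counts_table`.
#' @param sites the `lox_site_table`.
#' @param open_regions optional `interval_set` (0-based half-open).
#' @param centromeres optional `centromere_table`.
#' @param normalization passed to [compute_arr()].
#' @return a `site_rates` data frame.
#' @export
compute_site_rates <- function(counts, sites, open_regions = NULL,
                               centromeres = NULL,
                               normalization = "partners") {
  rr <- compute_rr(counts)
  ai <- compute_arr(counts, sites, "intra", normalization)
  ae <- compute_arr(counts, sites, "inter", normalization)
  i <- match(rr$site_id, sites$site_id)
  open <- rep(NA, nrow(rr))
  if (!is.null(open_regions)) {
    open <- vapply(seq_len(nrow(rr)), function(k) {
      p0 <- sites$position[i[k]] - 1L # 0-based
      any(open_regions$chrom == sites$chrom[i[k]] &
            open_regions$start <= p0 & p0 < open_regions$end)
    }, logical(1))
  }
  arm <- rep(NA_character_, nrow(rr))
  if (!is.null(centromeres)) {
    ci <- match(sites$chrom[i], centromeres$chrom)
    arm <- ifelse(sites$position[i] < centromeres$cen_start[ci], "L",
                  ifelse(sites$position[i] > centromeres$cen_end[ci], "R",
                         "C"))
  }
  out <- data.frame(site_id = rr$site_id, chrom = sites$chrom[i],
                    position = sites$position[i], rr = rr$rr,
                    arr_intra = ai$arr, arr_inter = ae$arr,
                    open_chromatin = open, arm = arm,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_rates", "data.frame")
  out
}

group_test_result <- function(test, statistic, p_value, n1, n2) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), n1 = n1, n2 = n2),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %d vs %d)\n", x$test,
              x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Group comparisons of ARR
#'
#' Two standard contrasts: intra- vs inter-chromosomal ARR (two-sided
#' Mann-Whitney, normal approximation with tie correction) and
#' open- vs closed-chromatin inter-chromosomal ARR (unpaired two-tailed
#' t-test).
#'
#' @param site_rates a `site_rates` table ([compute_site_rates()]).
#' @return named list of `group_test_result`s (`intra_vs_inter`, and
#'   `open_vs_closed` when the open-chromatin flag is present).
#' @export
group_tests <- function(site_rates) {
  out <- list()
  gi <- site_rates$arr_intra[!is.na(site_rates$arr_intra)]
  ge <- site_rates$arr_inter[!is.na(site_rates$arr_inter)]
  if (!length(gi)) stop("group 'intra' is empty")
  if (!length(ge)) stop("group 'inter' is empty")
  mw <- suppressWarnings(stats::wilcox.test(gi, ge, exact = FALSE,
                                            correct = FALSE))
  if (all(c(gi, ge) == c(gi, ge)[1])) # fully tied data: no evidence
    mw <- list(statistic = mw$statistic, p.value = 1)
  out$intra_vs_inter <- group_test_result("mann_whitney", mw$statistic,
                                          mw$p.value, length(gi),
                                          length(ge))
  if (!all(is.na(site_rates$open_chromatin))) {
    op <- site_rates$arr_inter[site_rates$open_chromatin %in% TRUE]
    cl <- site_rates$arr_inter[site_rates$open_chromatin %in% FALSE]
    op <- op[!is.na(op)]; cl <- cl[!is.na(cl)]
    if (!length(op)) stop("group 'open' is empty")
    if (!length(cl)) stop("group 'closed' is empty")
    tt <- stats::t.test(op, cl, var.equal = TRUE)
    out$open_vs_closed <- group_test_result("t_test_two_tailed",
                                            tt$statistic, tt$p.value,
                                            length(op), length(cl))
  }
  out
}

#' Correlation of RW with chromatin contact counts
#'
#' Spearman correlation over inter-chromosomal locus pairs between RW and
#' the contact value of the bin pair containing each locus pair.
#'
#' @param rw an `rw_matrix`.
#' @param contact numeric matrix indexed like `rw` (same loci).
#' @param sites the `lox_site_table`.
#' @return a `group_test_result` with test `"spearman"`; statistic is rho
#'   (`NA` for degenerate input).
#' @export
contact_correlation <- function(rw, contact, sites) {
  if (!all(dim(rw) == dim(contact)))
    stop("contact matrix dimensions do not match RW matrix")
  long <- rw_long(rw, sites)
  inter <- long[long$class == "inter", ]
  cv <- contact[cbind(match(inter$site_a, rownames(rw)),
                      match(inter$site_b, rownames(rw)))]
  if (length(unique(cv)) < 2 || length(unique(inter$rw)) < 2)
    return(group_test_result("spearman", NA_real_, NA_real_,
                             nrow(inter), nrow(inter)))
  ct <- suppressWarnings(stats::cor.test(inter$rw, cv,
                                         method = "spearman"))
  group_test_result("spearman", ct$estimate, ct$p.value, nrow(inter),
                    nrow(inter))
}

#' Normalised log2 ratio of two contact maps
#'
#' `log2(A / B)` centred by subtracting the median over cells where both
#' maps are positive; masked cells are `NA`.
#'
#' @param mapA,mapB positive numeric matrices of equal dimension.
#' @return matrix of median-centred log2 ratios.
#' @export
contact_ratio_map <- function(mapA, mapB) {
  if (!all(dim(mapA) == dim(mapB))) stop("contact map shape mismatch")
  ok <- mapA > 0 & mapB > 0
  out <- matrix(NA_real_, nrow(mapA), ncol(mapA), dimnames = dimnames(mapA))
  lr <- log2(mapA[ok] / mapB[ok])
  out[ok] <- lr - stats::median(lr)
  out
}

#' Export rearrangement networks as weighted edge lists
#'
#' Writes two SIF-style TSV edge lists (`source`, `interaction`, `target`,
#' `weight`) of locus pairs with `RW >= threshold`: one intra- and one
#' inter-chromosomal, ready for import into network viewers.
#'
#' @param rw an `rw_matrix`.
#' @param sites the `lox_site_table`.
#' @param threshold minimum RW (>= 0).
#' @param path_prefix output prefix; files `<prefix>_intra.sif` and
#'   `<prefix>_inter.sif`.
#' @return named character vector of the two paths, invisibly.
#' @export
export_network <- function(rw, sites, threshold, path_prefix) {
  stopifnot(threshold >= 0)
  long <- rw_long(rw, sites)
  keep <- long[long$rw >= threshold & long$rw > 0, , drop = FALSE]
  paths <- c(intra = paste0(path_prefix, "_intra.sif"),
             inter = paste0(path_prefix, "_inter.sif"))
  for (cl in c("intra", "inter")) {
    df <- keep[keep$class == cl,
               c("site_a", "site_b", "rw"), drop = FALSE]
    out <- data.frame(source = df$site_a,
                      interaction = rep("rearrangement", nrow(df)),
                      target = df$site_b, weight = df$rw,
                      stringsAsFactors = FALSE)
    write_report(out, paths[[cl]], sort_by = c("source", "target"))
  }
  invisible(paths)
}
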