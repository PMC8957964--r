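test_that("predictor distributions count and proportion correctly", {
  ann <- data.frame(probe_id = paste0("p", 1:4),
                    chr = c("1", "1", "2", "5"), pos = 1:4,
                    gene = "",
                    region_group = c("Body", "Body", "TSS200", "IGR"),
                    cgi_relation = c("island", "shore", "shore",
                                     "open_sea"),
                    snp_flag = FALSE, stringsAsFactors = FALSE)
  d <- summarize_predictor_distribution(paste0("p", 1:4), ann)
  rg <- d$region_group
  expect_equal(rg$proportion[rg$category == "Body"], 0.5)
  expect_equal(rg$proportion[rg$category == "TSS200"], 0.25)
  expect_equal(rg$proportion[rg$category == "IGR"], 0.25)
  # zero-count categories are reported explicitly
  expect_true("3'UTR" %in% rg$category)
  expect_identical(rg$count[rg$category == "3'UTR"], 0L)
  # proportions sum to 1 on every axis
  for (ax in names(d)) expect_equal(sum(d[[ax]]$proportion), 1,
                                    tolerance = 1e-12)
})

test_that("empty predictor sets warn; unannotated probes error", {
  ann <- toy_annotation(toy_beta(3, 2))
  expect_warning(d <- summarize_predictor_distribution(character(0), ann),
                 "empty")
  expect_identical(nrow(d$chromosome), 0L)
  expect_error(summarize_predictor_distribution("nope", ann),
               "unannotated")
})

test_that("distribution matches an independent tally on simulated data", {
  cfg <- synth_config(n_samples = 10, n_probes = 800, n_causal = 0,
                      missing_rate = 0, seed = 36)
  refs <- simulate_reference_profiles(800, 20, delta = 0.8, seed = 36)
  coh <- simulate_cohort(cfg, refs)
  probes <- sample(coh$annotation$probe_id, 100)
  d <- summarize_predictor_distribution(probes, coh$annotation)
  sub <- coh$annotation[match(probes, coh$annotation$probe_id), ]
  for (cat in unique(sub$region_group)) {
    expect_identical(
      d$region_group$count[d$region_group$category == cat],
      sum(sub$region_group == cat))
  }
})

test_that("identical tumor/adjacent matrices yield a null DMP result", {
  b <- toy_beta(20, 10, seed = 37)
  colnames(b) <- paste0("T", 1:10)
  adj <- b
  colnames(adj) <- paste0("N", 1:10)
  pairs <- data.frame(tumor = paste0("T", 1:10),
                      adjacent = paste0("N", 1:10))
  res <- paired_dmp_test(b, adj, pairs)
  expect_true(all(res$t_stat == 0))
  expect_true(all(res$direction == "ns"))
})

test_that("a shifted probe is flagged hyper with the closed-form t", {
  set.seed(38)
  n_pairs <- 10
  base <- toy_beta(15, n_pairs, seed = 38) * 0.4 + 0.2
  colnames(base) <- paste0("N", 1:n_pairs)
  tum <- base + matrix(rnorm(length(base), 0, 0.01), nrow = 15)
  tum[3, ] <- tum[3, ] + 0.2
  colnames(tum) <- paste0("T", 1:n_pairs)
  pairs <- data.frame(tumor = paste0("T", 1:n_pairs),
                      adjacent = paste0("N", 1:n_pairs))
  res <- paired_dmp_test(tum, base, pairs)
  expect_identical(res$direction[3], "hyper")
  oracle <- paired_t_oracle(tum[3, ], base[3, ])
  expect_equal(res$t_stat[3], oracle$t, tolerance = 1e-10)
  expect_equal(res$p_value[3], oracle$p, tolerance = 1e-10)
  # BH across all probes matches the hand-rolled step-up
  expect_equal(res$q_value, bh_oracle(res$p_value), tolerance = 1e-12)
})

test_that("BH agrees with the hand-applied step-up on a known vector", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("pairing errors are reported", {
  b <- toy_beta(5, 4, seed = 39)
  pairs <- data.frame(tumor = colnames(b)[1:3], adjacent = c("x", "y", "z"))
  expect_error(paired_dmp_test(b, b, pairs), "unmatched")
  expect_error(paired_dmp_test(b, b, pairs[1:2, ]), "3")
})

test_that("correlation screen flags strictly above the threshold", {
  score <- c(1, 2, 3, 4, 5)
  feats <- rbind(equal = score, anti = -score,
                 at_threshold = c(4, 1, 3, 2, 5))
  colnames(feats) <- paste0("S", 1:5)
  names(score) <- paste0("S", 1:5)
  res <- correlate_features_with_score(feats, score)
  expect_equal(res$r[res$feature_id == "equal"], 1)
  expect_true(res$flagged[res$feature_id == "equal"])
  expect_equal(res$r[res$feature_id == "anti"], -1)
  expect_true(res$flagged[res$feature_id == "anti"])
  # ranks (1..5) vs (4,1,3,2,5): sum d^2 = 14, rho = 1 - 84/120 = 0.3
  expect_equal(res$r[res$feature_id == "at_threshold"], 0.3,
               tolerance = 1e-12)
  expect_false(res$flagged[res$feature_id == "at_threshold"])
})

test_that("constant features are reported, never dropped", {
  feats <- rbind(ok = c(1, 3, 2, 5, 4), flat = rep(2, 5))
  res <- correlate_features_with_score(feats, c(1, 2, 3, 4, 5))
  expect_identical(nrow(res), 2L)
  expect_true(is.na(res$r[2]))
  expect_match(res$note[2], "constant")
})

test_that("correlation screens are sample-order invariant", {
  set.seed(40)
  feats <- matrix(runif(40), nrow = 4,
                  dimnames = list(paste0("f", 1:4), paste0("S", 1:10)))
  score <- setNames(runif(10), paste0("S", 1:10))
  r1 <- correlate_features_with_score(feats, score)
  perm <- sample(10)
  r2 <- correlate_features_with_score(feats[, perm], score)
  expect_equal(r1, r2)
})

test_that("methylation-expression screen honours the mapping contract", {
  set.seed(41)
  n <- 30
  beta <- matrix(runif(3 * n), nrow = 3,
                 dimnames = list(paste0("p", 1:3), paste0("S", 1:n)))
  # expression monotone decreasing in beta for mapped genes
  expr <- rbind(g1 = 10 - 6 * beta[1, ], g2 = 8 - 4 * beta[2, ])
  colnames(expr) <- paste0("S", 1:n)
  mapping <- c(p1 = "g1", p2 = "g2", p3 = "")   # p3 unmapped (IGR)
  res <- correlate_methylation_expression(beta, expr, mapping)
  expect_true(all(res$r < 0))
  expect_true(all(res$negative_flag))
  expect_false("p3" %in% res$probe_id)
  expect_identical(attr(res, "skipped"), "p3")
  expect_error(correlate_methylation_expression(beta, expr,
                                                c(p3 = "")), "no probe")
  expect_error(correlate_methylation_expression(beta, expr,
                                                c(p1 = "missing_gene")),
               "absent")
})

test_that("promoter-coupled genes show more negative correlation than decoupled", {
  cfg <- synth_config(n_samples = 120, n_probes = 600, n_causal = 0,
                      missing_rate = 0, seed = 42)
  refs <- simulate_reference_profiles(600, 30, delta = 0.8, seed = 42)
  coh <- simulate_cohort(cfg, refs)
  ann <- coh$annotation
  genic <- nzchar(ann$gene)
  mapping <- setNames(ann$gene[genic], ann$probe_id[genic])
  res <- correlate_methylation_expression(coh$beta, coh$expression,
                                          mapping)
  promoter <- ann$region_group[match(res$probe_id, ann$probe_id)] %in%
    c("TSS200", "TSS1500")
  expect_gt(mean(res$negative_flag[promoter]),
            mean(res$negative_flag[!promoter]))
})
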