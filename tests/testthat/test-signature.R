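test_that("coherent-probe selection finds the maximal positively correlated subset", {
  set.seed(41)
  base <- rnorm(30)
  # duplicated rows of one vector: all retained
  m <- toy_matrix(rbind(base, base, base), features = c("a", "b", "c"))
  expect_equal(select_coherent_probes(m, c("a", "b", "c")), c("a", "b", "c"))

  # C = -A is anti-correlated, B = A + small noise coheres with A
  m2 <- toy_matrix(rbind(base, base + rnorm(30, sd = 0.1), -base),
                   features = c("A", "B", "C"))
  expect_equal(select_coherent_probes(m2, c("A", "B", "C")), c("A", "B"))

  # exhaustive-oracle check on random probe sets: the selected subset is
  # valid (all pairwise r > threshold) and no larger valid subset exists
  for (i in 1:10) {
    k <- sample(3:6, 1)
    v <- matrix(rnorm(k * 20), k, 20)
    v[seq_len(k %/% 2), ] <- rep(rnorm(20), each = k %/% 2) +
      matrix(rnorm(k %/% 2 * 20, sd = 0.4), k %/% 2, 20)
    mm <- toy_matrix(v, features = paste0("q", 1:k))
    sel <- select_coherent_probes(mm, paste0("q", 1:k), r_pair_min = 0.5)
    cc <- cor(t(v)); rownames(cc) <- colnames(cc) <- paste0("q", 1:k)
    valid <- function(s) length(s) == 1 ||
      all(cc[s, s][upper.tri(cc[s, s])] > 0.5)
    expect_true(valid(sel))
    bigger <- unlist(lapply((length(sel) + 1):k, function(sz) {
      if (sz > k) return(FALSE)
      combn(paste0("q", 1:k), sz, valid)
    }))
    expect_false(any(bigger))
  }
  expect_error(select_coherent_probes(m, "zz"), "no target probe")
})

test_that("probe screen equals brute-force per-pair recomputation", {
  set.seed(42)
  d <- suppressMessages(simulate_exon_dataset(
    synthetic_config(n_samples = 20, n_module_genes = 15,
                     n_background_genes = 40, probes_per_gene = 2,
                     seed = 5)))
  m <- d$matrix
  targets <- c("MYC_p1", "MYC_p2")
  params <- screen_params()
  kept <- suppressMessages(screen_probes(m, targets, params))
  expect_true(all(targets %in% kept))
  v <- unclass(m)
  brute <- rownames(v)[vapply(rownames(v), function(pb) {
    if (sd(v[pb, ]) == 0) return(FALSE)
    any(vapply(targets, function(tg) {
      ct <- cor.test(v[pb, ], v[tg, ])
      abs(ct$estimate) >= params$r_min && ct$p.value < params$p_max
    }, logical(1)))
  }, logical(1))]
  expect_setequal(kept, brute)
  expect_error(screen_probes(m, character(0)), "no retained")
})

test_that("median/IQR standardisation is exact, idempotent, and drops flat rows", {
  m <- toy_matrix(rbind(c(1, 2, 3, 4, 5), c(10, 10, 10, 10, 10)),
                  features = c("a", "flat"))
  expect_warning(std <- robust_standardize(m), "zero IQR")
  expect_equal(unname(unclass(std)["a", ]), c(-1, -0.5, 0, 0.5, 1))
  expect_false("flat" %in% rownames(std))
  # idempotence: a standardised row is a fixed point
  std2 <- robust_standardize(std)
  expect_equal(unclass(std2)[, ], unclass(std)[, ])
  # exactness on random rows
  set.seed(43)
  r <- toy_matrix(matrix(rnorm(60), 6, 10))
  s <- robust_standardize(r)
  expect_equal(unname(apply(unclass(s), 1, median)), rep(0, 6))
  expect_equal(unname(apply(unclass(s), 1, IQR)), rep(1, 6))
  expect_error(robust_standardize(toy_matrix(matrix(1, 2, 4))), "zero IQR")
})

test_that("probe-to-gene aggregation is the per-gene mean of standardized probes", {
  v <- rbind(c(0.2, 1), c(0.4, 3), c(-1, 0))
  m <- toy_matrix(v, features = c("p1", "p2", "p3"))
  ann <- probe_annotation(c("p1", "p2", "p3"), c("GA", "GA", "GB"))
  g <- aggregate_probes(m, ann)
  expect_equal(unname(unclass(g)["GA", ]), c(0.3, 2))
  expect_equal(unname(unclass(g)["GB", ]), c(-1, 0))  # single probe: identity
  # random annotation vs a per-gene loop oracle
  set.seed(44)
  big <- toy_matrix(matrix(rnorm(200), 20, 10))
  genes <- paste0("G", sample(1:6, 20, replace = TRUE))
  ann2 <- probe_annotation(rownames(big), genes)
  agg <- aggregate_probes(big, ann2)
  for (gn in unique(genes)) {
    expected <- colMeans(unclass(big)[genes == gn, , drop = FALSE])
    expect_equal(unname(unclass(agg)[gn, ]), unname(expected))
  }
  # unannotated probes dropped with a count; nothing mapped is an error
  ann3 <- probe_annotation("p1", "GA")
  expect_message(aggregate_probes(m, ann3), "2 unannotated")
  expect_error(aggregate_probes(m, probe_annotation("zz", "GA")),
               "no probe maps")
})

test_that("exon-array fit composes the stages and records verifiable counts", {
  d <- suppressMessages(simulate_exon_dataset(
    synthetic_config(n_samples = 30, n_module_genes = 25,
                     n_background_genes = 60, probes_per_gene = 3,
                     seed = 6)))
  fit <- suppressMessages(exon_signature(d$matrix, d$annotation, "MYC"))
  expect_s3_class(fit, "driver_signature")
  # decorrelated driver probe rejected
  expect_equal(fit$counts[["retained_target_probes"]], 5)
  expect_false(d$truth$decorrelated_probe %in% fit$retained_target_probes)
  # screened set contains the retained driver probes
  expect_true(all(fit$retained_target_probes %in% fit$screened_probes))
  # every signature gene's record satisfies the thresholds on recomputation
  rec <- fit$records[fit$records$gene_symbol %in% fit$signature_genes, ]
  for (i in seq_len(nrow(rec))) {
    r <- naive_pearson(unclass(fit$gene_matrix)[rec$gene_symbol[i], ],
                       fit$reference)
    expect_equal(rec$r[i], r, tolerance = 1e-12)
    expect_true(abs(r) >= fit$params$r_min)
    expect_true(cor_pvalue(r, rec$n[i]) < fit$params$p_max)
  }
  # driver excluded by default, included on request
  expect_false("MYC" %in% fit$signature_genes)
  fit2 <- suppressMessages(exon_signature(d$matrix, d$annotation, "MYC",
                                          exclude_target = FALSE))
  expect_true("MYC" %in% fit2$signature_genes)
  expect_error(suppressMessages(
    exon_signature(d$matrix, d$annotation, "NOSUCH")), "no annotated probe")
})

test_that("fit is invariant to feature and sample permutations of the input", {
  d <- suppressMessages(simulate_exon_dataset(
    synthetic_config(n_samples = 25, n_module_genes = 20,
                     n_background_genes = 40, probes_per_gene = 2,
                     seed = 7)))
  fit <- suppressMessages(exon_signature(d$matrix, d$annotation, "MYC"))
  v <- unclass(d$matrix)
  set.seed(45)
  vp <- v[sample(nrow(v)), sample(ncol(v))]
  mp <- expr_matrix(vp, scale = "log")
  fitp <- suppressMessages(exon_signature(mp, d$annotation, "MYC"))
  expect_equal(fitp$counts, fit$counts)
  expect_setequal(fitp$signature_genes, fit$signature_genes)
  expect_setequal(fitp$screened_probes, fit$screened_probes)
})

test_that("tightening either threshold never grows the signature", {
  d <- suppressMessages(simulate_exon_dataset(
    synthetic_config(n_samples = 25, n_module_genes = 20,
                     n_background_genes = 60, probes_per_gene = 2,
                     beta = 0.6, seed = 8)))
  grid_r <- c(0.3, 0.5, 0.7)
  grid_p <- c(0.05, 0.01, 0.001)
  sigs <- lapply(grid_r, function(rm) lapply(grid_p, function(pm)
    suppressMessages(exon_signature(
      d$matrix, d$annotation, "MYC",
      params = screen_params(r_min = rm, p_max = pm)))$signature_genes))
  for (i in seq_along(grid_r)) for (j in seq_along(grid_p)) {
    if (i < length(grid_r))
      expect_true(all(sigs[[i + 1]][[j]] %in% sigs[[i]][[j]]))
    if (j < length(grid_p))
      expect_true(all(sigs[[i]][[j + 1]] %in% sigs[[i]][[j]]))
  }
})

test_that("gene-level fit correlates rows directly and honours the p cutoff", {
  set.seed(46)
  n <- 6
  ref <- rnorm(n)
  # genes built with exact sample correlations straddling the cutoff
  make_gene <- function(target_r) {
    z1 <- scale(ref)[, 1]
    e <- residuals(lm(rnorm(n) ~ ref))
    target_r * z1 + sqrt(1 - target_r^2) * e / sd(e)
  }
  cut <- effective_r_cutoff(n, 0.05)
  rs <- c(0.45, 0.6, cut - 0.01, cut + 0.01, 0.95)
  v <- t(vapply(rs, make_gene, numeric(n)))
  m <- expr_matrix(rbind(ref, v),
                   feature_ids = c("DRV", paste0("g", seq_along(rs))),
                   sample_ids = paste0("s", 1:n), scale = "linear")
  fit <- gene_signature(m, "DRV")
  got <- fit$records[match(paste0("g", seq_along(rs)),
                           fit$records$gene_symbol), ]
  expect_equal(got$r, rs, tolerance = 1e-9)
  # genes between r_min and the p-implied cutoff are rejected: the
  # significance threshold binds at n = 6
  expect_equal(got$passes, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_false("DRV" %in% fit$signature_genes)
  expect_true(fit$records$passes[fit$records$gene_symbol == "DRV"])
  expect_error(gene_signature(m, "NOSUCH"), "absent")
})
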