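test_that("select_signature keeps the most variant CGIs with deterministic ties", {
  set.seed(1)
  n <- 100
  sds <- seq(0.01, 0.5, length.out = n)
  beta <- t(sapply(seq_len(n), function(i) .5 + sds[i] * scale(rnorm(30))[, 1] / 5))
  beta <- pmin(pmax(beta, 0), 1)
  dim(beta) <- c(n, 30)
  dimnames(beta) <- list(sprintf("CGI%03d", 1:n), sprintf("S%02d", 1:30))
  sig <- select_signature(beta, 0.05)
  expect_length(sig$cgi_ids, 5L)
  v <- apply(beta, 1, var)
  expect_setequal(sig$cgi_ids, names(sort(v, decreasing = TRUE))[1:5])

  expect_length(select_signature(beta, 1)$cgi_ids, n)  # fraction 1: everything
  expect_length(select_signature(beta, 0.001)$cgi_ids, 1L)  # ceiling >= 1

  # exact tie at the cutoff: lexicographically smaller id wins
  tied <- rbind(a_cgi = c(0, 1, 0, 1), z_cgi = c(1, 0, 1, 0),
                b_cgi = c(.5, .5, .5, .5))
  colnames(tied) <- paste0("s", 1:4)
  sig2 <- select_signature(tied, fraction = 1 / 3)
  expect_identical(sig2$cgi_ids, "a_cgi")

  expect_error(select_signature(beta[, 1, drop = FALSE]), "2 samples")
  expect_error(select_signature(beta, 0), "fraction")
})

test_that("call_cimp labels the hypermethylated cluster positive and recovers separable blocks", {
  beta <- two_block_beta(n1 = 4, n2 = 6)
  sig <- make_signature(rownames(beta))
  call <- call_cimp(beta, sig)
  expect_identical(unname(as.character(call$label[1:4])), rep("negative", 4))
  expect_identical(unname(as.character(call$label[5:10])), rep("positive", 6))
  expect_gt(call$cluster_mean_methylation["positive"],
            call$cluster_mean_methylation["negative"])

  # labels follow samples under column permutation
  perm <- sample(ncol(beta))
  call_perm <- call_cimp(beta[, perm], sig)
  expect_identical(as.character(call_perm$label[call$sample_ids]),
                   as.character(call$label))

  expect_error(call_cimp(beta, sig, k = 11), "exceeds")
  flat <- beta; flat[] <- 0.5
  expect_error(call_cimp(flat, sig), "no methylation variation")
})

test_that("the positive class always has higher mean signature methylation", {
  for (s in 1:8) {
    set.seed(s)
    beta <- matrix(runif(30 * 20), 30, 20,
                   dimnames = list(sprintf("CGI%03d", 1:30), sprintf("S%02d", 1:20)))
    call <- call_cimp(beta, select_signature(beta, 0.2))
    pos <- names(call$label)[call$label == "positive"]
    neg <- names(call$label)[call$label == "negative"]
    sub <- beta[call$signature$cgi_ids, , drop = FALSE]
    expect_gt(mean(sub[, pos]), mean(sub[, neg]))
  }
})

test_that("consensus entries are exact on ideal blocks and A(2) matches the closed form", {
  beta <- two_block_beta(n1 = 2, n2 = 4)  # 6 samples for enumeration
  sig <- make_signature(rownames(beta))
  prof <- consensus_cluster(beta, sig, k_range = 2:3, n_resamples = 40,
                            subsample_fraction = 1, seed = 1)
  cm <- prof$per_k[["2"]]$consensus
  entries <- cm[upper.tri(cm)]
  expect_true(all(entries %in% c(0, 1)))  # deterministic clusterer, full subsample
  expect_equal(prof$areas[["2"]], block_area_closed_form(2, 4), tolerance = 1e-12)

  # direct enumeration over the 15 sample pairs agrees with the closed form
  labels <- rep(1:2, c(2, 4))
  pairs <- combn(6, 2)
  manual_area <- mean(labels[pairs[1, ]] != labels[pairs[2, ]])
  expect_equal(prof$areas[["2"]], manual_area, tolerance = 1e-12)

  # with subsampling, entries stay 0/1 and the matrix is symmetric in [0,1]
  prof2 <- consensus_cluster(beta, sig, k_range = 2:2, n_resamples = 60,
                             subsample_fraction = 0.8, seed = 2)
  cm2 <- prof2$per_k[["2"]]$consensus
  expect_equal(cm2, t(cm2))
  expect_true(all(cm2[!is.na(cm2)] >= 0 & cm2[!is.na(cm2)] <= 1))
  expect_true(all(diag(cm2)[!is.na(diag(cm2))] == 1))
  # CDF is monotone with CDF(1) = 1
  expect_true(all(diff(prof2$per_k[["2"]]$cdf) >= 0))
  expect_equal(tail(prof2$per_k[["2"]]$cdf, 1), 1)
})

test_that("delta_k implements the relative-increase criterion", {
  expect_equal(delta_k(c("2" = 0.5, "3" = 0.5)), c("2" = 0.5, "3" = 0))
  expect_equal(delta_k(c("2" = 0.4, "3" = 0.6)), c("2" = 0.4, "3" = 0.5))
  expect_equal(delta_k(c("2" = 0.5)), c("2" = 0.5))
  expect_error(delta_k(c("2" = 0, "3" = 0.2)), "undefined")
  expect_error(delta_k(c("3" = 0.2)), "starting at 2")
})

test_that("signature size has little effect on a strongly planted two-class structure", {
  ds <- simulate_dataset(simulation_config(n_tissues = 1, n_genes = 30, seed = 9))
  cgi <- dataset_cgi(ds, "tissue01")
  stab <- signature_stability(cgi, fractions = seq(0.01, 0.10, by = 0.01))
  expect_equal(stab$ari[stab$fraction == 0.05], 1)  # reference vs itself
  expect_gte(min(stab$ari), 0.8)
})

test_that("signature stability is at chance on signal-free data", {
  aris <- vapply(1:20, function(s) {
    set.seed(s)
    beta <- matrix(rbeta(150 * 40, 2, 5), 150, 40,
                   dimnames = list(sprintf("CGI%03d", 1:150), sprintf("S%02d", 1:40)))
    stab <- signature_stability(beta, fractions = c(0.02, 0.08))
    mean(stab$ari)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.15)
})
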