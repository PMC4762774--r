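chain_graph <- function(coords, elements = NULL, h = NULL) {
  n <- nrow(coords)
  if (is.null(elements)) elements <- rep("C", n)
  if (is.null(h)) h <- rep(0L, n)
  molecular_graph("chain",
                  data.frame(label = paste0("A", 1:n), element = elements,
                             h_count = h, x = coords[, 1], y = coords[, 2],
                             z = coords[, 3]),
                  data.frame(i = seq_len(n - 1), j = seq_len(n - 1) + 1,
                             order = 1L))
}

test_that("spatial distances: bond-path vs euclidean", {
  # two bonded atoms: both modes give the bond length
  g2 <- chain_graph(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(spatial_distance_matrix(g2, "bond-path")[1, 2], 1.5)
  expect_equal(spatial_distance_matrix(g2, "euclidean")[1, 2], 1.5)
  # collinear A-B-C: both give 2
  g3 <- chain_graph(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(spatial_distance_matrix(g3, "bond-path")[1, 3], 2)
  expect_equal(spatial_distance_matrix(g3, "euclidean")[1, 3], 2)
  # bent 120-degree A-B-C, unit bonds: path 2, through-space sqrt(3)
  bent <- chain_graph(rbind(c(0, 0, 0), c(1, 0, 0),
                            c(1 + cos(pi / 3), sin(pi / 3), 0)))
  expect_equal(spatial_distance_matrix(bent, "bond-path")[1, 3], 2)
  expect_equal(spatial_distance_matrix(bent, "euclidean")[1, 3], sqrt(3),
               tolerance = 1e-12)
  # error contracts
  gna <- g2; gna$atoms$x[2] <- NA
  expect_error(spatial_distance_matrix(gna), "A2")
})

test_that("bond-path distances are symmetric, positive, metric", {
  d <- spatial_distance_matrix(idealized_geometry(c(1, 4, 6)))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:5)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("extension matrix: both strategies on hand-checked input", {
  d3 <- rbind(c(0, 1), c(1, 0))
  s_diag <- extension_matrix(d3, c(2, 3), c(4, 5), "diagonal")
  expect_equal(unname(s_diag), rbind(c(0, 15), c(8, 0)), ignore_attr = TRUE)
  s_lit <- extension_matrix(d3, c(2, 3), c(4, 5), "literal")
  expect_equal(qr(s_lit)$rank, 1)    # outer-product structure
  # n = 1 degenerate case
  expect_equal(unname(extension_matrix(matrix(0, 1, 1), 2, 3, "diagonal")),
               matrix(0, 1, 1), ignore_attr = TRUE)
  expect_equal(unname(extension_matrix(matrix(0, 1, 1), 2, 3, "literal")),
               matrix(0, 1, 1), ignore_attr = TRUE)
  expect_error(extension_matrix(d3, c(2, 3, 4), c(4, 5)), "length")
})

test_that("correction matrix is the Gram matrix of S", {
  expect_equal(correction_matrix(diag(3)), diag(3))
  s <- rbind(c(0, 15), c(8, 0))
  expect_equal(correction_matrix(s), rbind(c(225, 0), c(0, 64)))
  set.seed(7)
  for (rep in 1:10) {
    s <- matrix(rnorm(36), 6, 6)
    q <- correction_matrix(s)
    expect_equal(q, t(q), tolerance = 1e-12)
    lam <- eigen(q, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(lam), -1e-8 * max(abs(lam)))
  }
  expect_error(correction_matrix(matrix(1, 2, 3)), "square")
})

test_that("spectrum extraction sorts ascending and guards imaginary parts", {
  expect_equal(q_spectrum(diag(c(3, 1, 2)))$eigenvalues, c(1, 2, 3))
  sp <- q_spectrum(rbind(c(0, 1), c(1, 0)))
  expect_equal(sp$eigenvalues, c(-1, 1))
  expect_true(sp$symmetric_input)
  # rotation matrix has eigenvalues +/- i: must refuse
  rot <- rbind(c(0, -1), c(1, 0))
  expect_error(q_spectrum(rot), "imaginary")
  # mildly asymmetric matrix with real spectrum is accepted
  m <- rbind(c(2, 1e-12), c(0, 1))
  sp2 <- q_spectrum(m)
  expect_equal(sp2$eigenvalues, c(1, 2))
})

test_that("xp indices are the absolute extreme eigenvalues", {
  expect_equal(unname(xp_indices(fixture_spectrum())), c(9.3541, 58.2157))
  expect_equal(unname(xp_indices(c(0))), c(0, 0))
  expect_equal(unname(xp_indices(c(-3, 2))), c(3, 2))
  expect_error(xp_indices(numeric(0)), "empty")
})

test_that("pipeline Q is symmetric PSD on every congener, both strategies", {
  pats <- c(list(integer(0)), enumerate_patterns())
  for (strategy in c("diagonal", "literal")) {
    worst <- Inf
    second_rel <- -Inf
    for (p in pats) {
      mats <- descriptor_matrices(idealized_geometry(p), strategy = strategy)
      lam <- eigen(mats$q, symmetric = TRUE, only.values = TRUE)$values
      worst <- min(worst, min(lam) / max(lam))
      if (strategy == "literal")
        second_rel <- max(second_rel, sort(abs(lam), decreasing = TRUE)[2] / max(abs(lam)))
    }
    expect_gte(worst, -1e-8)
    if (strategy == "literal") expect_lte(second_rel, 1e-8)  # rank-1 Q
  }
})

test_that("indices are invariant under atom permutation", {
  set.seed(11)
  g <- idealized_geometry(c(1, 3, 8))
  ref <- compute_indices(g)
  for (rep in 1:5) {
    gp <- permute_graph(g, sample(n_atoms(g)))
    res <- compute_indices(gp)
    expect_equal(res$xp1, ref$xp1, tolerance = 1e-8 * max(1, ref$xp2))
    expect_equal(res$xp2, ref$xp2, tolerance = 1e-8)
    expect_equal(res$spectrum$eigenvalues, ref$spectrum$eigenvalues,
                 tolerance = 1e-6)
  }
})

test_that("indices are invariant under the scaffold mirror symmetry", {
  for (pat in list(c(2, 8), c(1, 2, 4), c(3), c(1, 2, 5, 6))) {
    a <- compute_indices(idealized_geometry(pat))
    b <- compute_indices(idealized_geometry(mirror_pattern(pat)))
    expect_equal(a$xp1, b$xp1, tolerance = 1e-8 * max(1, a$xp2))
    expect_equal(a$xp2, b$xp2, tolerance = 1e-10)
  }
})

test_that("eigenvalues scale as c^2 under distance scaling", {
  for (strategy in c("diagonal", "literal")) {
    g <- idealized_geometry(c(2, 7))
    lam <- q_spectrum(descriptor_matrices(g, strategy = strategy)$q)$eigenvalues
    for (c_scale in c(0.5, 2, 3.7)) {
      gs <- g
      gs$atoms[, c("x", "y", "z")] <- c_scale * gs$atoms[, c("x", "y", "z")]
      lam_s <- q_spectrum(descriptor_matrices(gs, strategy = strategy)$q)$eigenvalues
      # compare on the scale of the spectral radius: the near-zero eigenvalues
      # of the rank-deficient literal Q are numerical noise
      expect_lt(max(abs(lam_s - c_scale^2 * lam)) / max(abs(lam_s)), 1e-9)
    }
  }
})

test_that("mean XP2 grows with bromination under default options", {
  pats <- c(list(integer(0)), enumerate_patterns())
  xp2 <- vapply(pats, function(p) compute_indices(idealized_geometry(p))$xp2, 0)
  k <- vapply(pats, length, 0L)
  means <- tapply(xp2, k, mean)
  expect_true(all(diff(means) >= 0))
})

test_that("literal strategy yields one dominant eigenvalue end to end", {
  res <- compute_indices(idealized_geometry(c(2, 8)), strategy = "literal")
  expect_lte(res$xp1, 1e-8 * res$xp2)
  resd <- compute_indices(idealized_geometry(c(2, 8)))
  expect_gte(resd$xp1, 0)
  expect_gte(resd$xp2, resd$xp1)
})

test_that("index results serialize to JSON with their configuration", {
  res <- compute_indices(idealized_geometry("2,8"))
  js <- jsonlite::fromJSON(index_result_json(res))
  expect_equal(js$name, "2,8-DBXTH")
  expect_equal(js$xp2, res$xp2, tolerance = 1e-12)
  expect_equal(js$strategy, "diagonal")
  expect_length(js$eigenvalues, 17)
})
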