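# Shared helpers: brute-force oracles and synthetic fixtures built in code.

# brute-force PRESS: n explicit refits, each predicting the held-out row
brute_force_press <- function(table, property, descriptors = c("xp1", "xp2")) {
  dat <- table[stats::complete.cases(table[, c(property, descriptors)]), ]
  n <- nrow(dat)
  form <- stats::as.formula(paste(property, "~",
                                  paste(descriptors, collapse = " + ")))
  loo <- vapply(seq_len(n), function(i) {
    fit <- stats::lm(form, data = dat[-i, ])
    dat[[property]][i] - stats::predict(fit, newdata = dat[i, ])
  }, 0)
  sum(loo^2)
}

# random regression table with two descriptors and optional noise
make_toy_table <- function(n, seed, noise_sd = 1) {
  set.seed(seed)
  xp1 <- runif(n, 0, 50)
  xp2 <- xp1 * 2 + rnorm(n, sd = 10)
  data.frame(xp1 = xp1, xp2 = xp2,
             y = 5 + 1.5 * xp1 + 0.8 * xp2 + rnorm(n, sd = noise_sd))
}

# random group tree over the supported elements, depth <= max_depth
random_group_tree <- function(max_depth, p_branch = 0.6) {
  elems <- c("H", "C", "N", "O", "Br", "I")
  root <- sample(elems, 1)
  if (max_depth == 0 || runif(1) > p_branch) return(group_tree(root))
  k <- sample(1:3, 1)
  kids <- replicate(k, random_group_tree(max_depth - 1, p_branch),
                    simplify = FALSE)
  do.call(group_tree, c(list(root), kids))
}

# all Pauling values of atoms in a tree (for convexity bounds)
tree_elements <- function(tree) {
  c(tree$element, unlist(lapply(tree$children, tree_elements)))
}

# relabel a graph's atoms by a permutation (new index of old atom i is perm[i])
permute_graph <- function(graph, perm) {
  inv <- order(perm)
  atoms <- graph$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- data.frame(i = inv[graph$bonds$i], j = inv[graph$bonds$j],
                      order = graph$bonds$order)
  molecular_graph(graph$name, atoms, bonds)
}
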