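test_that("fused feature length is the sum of the enabled branch dims", {
  expect_equal(fused_length(model_config(complex_dim = 128, ligand_dim = 32)), 160)
  expect_equal(fused_length(model_config(complex_dim = 16, ligand_dim = 16)), 32)
  cfg <- model_config(complex_dim = 128)
  expect_equal(fused_length(ablation_variant(cfg, "complex_only")), 128)
  expect_equal(fused_length(ablation_variant(model_config(ligand_dim = 16),
                                             "ligand_only")), 16)
  d <- 24
  expect_equal(fused_length(model_config(complex_dim = d, ligand_dim = d)), 2 * d)
  expect_equal(
    fused_length(model_config(complex_dim = 128, ligand_dim = 32, fp_dim = 64,
                              use_fingerprints = c("sifp", "ecif"))),
    224
  )
  expect_error(ablation_variant(model_config(), "both"), "unknown")
})

test_that("embeddings have the configured lengths", {
  ds <- small_dataset(2, seed = 81)
  cfg <- tiny_model_config(complex_dim = 12, ligand_dim = 7)
  samples <- featurize_dataset(ds, cfg)
  model <- init_model(cfg, 1)
  batch <- collate_batch(samples)
  fwc <- forward_complex(model$params, cfg, batch)
  expect_equal(dim(fwc$emb), c(2, 12))
  fwl <- forward_ligand(model$params, cfg, batch)
  expect_equal(dim(fwl$emb), c(2, 7))
  expect_true(all(is.finite(fwc$emb)))
  expect_true(all(is.finite(fwl$emb)))
})

test_that("encoders are permutation invariant", {
  ds <- small_dataset(1, seed = 82)
  cfg <- tiny_model_config()
  samples <- featurize_dataset(ds, cfg)
  model <- init_model(cfg, 2)
  p0 <- forward_model(model, collate_batch(samples))$preds
  set.seed(5)
  for (rep in 1:3) {
    s2 <- samples
    g <- s2[[1]]$complex
    newpos <- sample(g$num_nodes)
    g$node_features[newpos, ] <- s2[[1]]$complex$node_features
    g$edges <- matrix(newpos[s2[[1]]$complex$edges], ncol = 2)
    s2[[1]]$complex <- g
    gl <- s2[[1]]$ligand
    np <- sample(gl$num_nodes)
    gl$node_features[np, ] <- s2[[1]]$ligand$node_features
    gl$edges <- matrix(np[s2[[1]]$ligand$edges], ncol = 2)
    s2[[1]]$ligand <- gl
    expect_equal(forward_model(model, collate_batch(s2))$preds, p0,
                 tolerance = 1e-10)
  }
})

test_that("a single-node ligand graph depends only on that node", {
  m1 <- single_atom_molecule("N")
  cfg <- tiny_model_config(mode = "ligand_only")
  model <- init_model(cfg, 3)
  s <- list(list(ligand = build_ligand_graph(m1)))
  p1 <- forward_model(model, collate_batch(s))$preds
  # moving the atom changes nothing: no edges, features identical
  m2 <- single_atom_molecule("N", 5, 5, 5)
  s2 <- list(list(ligand = build_ligand_graph(m2)))
  expect_equal(forward_model(model, collate_batch(s2))$preds, p1)
})

test_that("the output head is linear: zero weights predict the label center", {
  ds <- small_dataset(3, seed = 83)
  cfg <- tiny_model_config()
  samples <- featurize_dataset(ds, cfg)
  model <- init_model(cfg, 1) # zero-initialized head
  model$label_center <- 5.5
  model$label_scale <- 2
  model$params$b_out <- 0
  expect_equal(forward_model(model, collate_batch(samples))$preds,
               rep(5.5, 3))
  model$params$b_out <- 1.25
  expect_equal(forward_model(model, collate_batch(samples))$preds,
               rep(5.5 + 1.25 * 2, 3))
})

test_that("forward is deterministic at eval and finite everywhere", {
  ds <- small_dataset(3, seed = 84)
  cfg <- tiny_model_config(use_fingerprints = "sifp")
  samples <- featurize_dataset(ds, cfg)
  model <- init_model(cfg, 7)
  model$params$w_out <- matrix(stats::rnorm(fused_length(cfg), sd = 0.1))
  b <- collate_batch(samples)
  p1 <- forward_model(model, b)$preds
  p2 <- forward_model(model, b)$preds
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
})

test_that("analytic gradients match central finite differences", {
  ds <- small_dataset(3, seed = 85)
  cfg <- tiny_model_config(use_fingerprints = "sifp", attention_heads = 2)
  samples <- featurize_dataset(ds, cfg)
  y <- attr(samples, "labels")
  model <- init_model(cfg, 3)
  set.seed(6)
  model$params$w_out <- matrix(stats::rnorm(fused_length(cfg), sd = 0.1))
  model$label_center <- mean(y)
  model$label_scale <- stats::sd(y)
  batch <- collate_batch(samples)
  lc <- loss_config("mse")
  fw <- forward_model(model, batch, training = TRUE) # dropout = 0 in config
  grads <- backward_model(model, batch, fw, loss_and_grad(fw$preds, y, lc)$grad)
  eps <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    ks <- if (length(p) > 6) sample(length(p), 6) else seq_along(p)
    for (k in ks) {
      m2 <- model
      m2$params[[nm]][k] <- p[k] + eps
      l1 <- loss_and_grad(forward_model(m2, batch)$preds, y, lc)$value
      m2$params[[nm]][k] <- p[k] - eps
      l0 <- loss_and_grad(forward_model(m2, batch)$preds, y, lc)$value
      num <- (l1 - l0) / (2 * eps)
      expect_equal(grads[[nm]][k], num, tolerance = 1e-4,
                   label = sprintf("grad of %s[%d]", nm, k))
    }
  }
})

test_that("parameter count is a pure function of the configuration", {
  cfg <- model_config(complex_dim = 128, ligand_dim = 32,
                      hidden_complex = 16, hidden_ligand = 32)
  n1 <- n_parameters(init_model(cfg, 1))
  n2 <- n_parameters(init_model(cfg, 999))
  expect_identical(n1, n2)
  # frozen regression value for the default architecture
  expect_identical(n_parameters(init_model(model_config(), 1)), 11941L)
})

test_that("inconsistent fingerprint branches are refused at inference", {
  ds <- small_dataset(2, seed = 86)
  cfg_fp <- tiny_model_config(use_fingerprints = "sifp")
  model <- init_model(cfg_fp, 1)
  plain <- featurize_dataset(ds, tiny_model_config())
  expect_error(forward_model(model, collate_batch(plain)),
               "expects fingerprints")
})

test_that("checkpoints round-trip and refuse version mismatches", {
  model <- init_model(tiny_model_config(), 5)
  path <- tempfile(fileext = ".rds")
  write_checkpoint(model, path)
  m2 <- read_checkpoint(path)
  expect_equal(m2$params, model$params)
  bad <- model
  bad$featurization <- "stale"
  saveRDS(bad, path)
  expect_error(read_checkpoint(path), "version mismatch")
})
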