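# Shared fixtures. Heavy objects (trained experiments) are built lazily
# and cached for the whole test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# A small database + prepared features used by several unit tests.
tiny_setup <- function() {
  cached("tiny", function() {
    cfg <- experiment_config(preset = "mini", master_seed = 401)
    spec <- database_spec("A", cfg$cultures$A, n_identities = 12,
                          noise_sd = 0.1, seed = 42, image_size = 64)
    net <- build_network(cfg$net)
    db <- generate_database(spec)
    data <- prepare_database(db, net, cfg$prep, cfg$aug)
    list(cfg = cfg, spec = spec, net = net, db = db, data = data)
  })
}

# One trained mini fit (single run), reused across trainer/probe tests.
tiny_fit <- function() {
  cached("tiny_fit", function() {
    ts <- tiny_setup()
    sp <- split_identities(ts$data$identities, ts$cfg$train$proportions,
                           seed = 7)
    tc <- ts$cfg$train
    fit <- train_run(init_fc_weights(ts$net, 11), ts$data, sp, tc,
                     run_seed = 13)
    list(fit = fit, split = sp)
  })
}

# Full mini experiments per master seed (the multi-seed replication
# scale; ~25 s each).
mini_experiment <- function(seed, fixture = "default-twin") {
  cached(sprintf("mini_%s_%d", fixture, seed), function() {
    run_full_experiment(fixture_suite(fixture, preset = "mini",
                                      master_seed = seed))
  })
}

# The desk-scale experiment (the single-seed reference scale, ~2 min).
desk_experiment <- function() {
  cached("desk_1", function() {
    run_full_experiment(fixture_suite("default-twin", preset = "desk",
                                      master_seed = 1))
  })
}

mean_matched <- function(rep) {
  mean(c(mean(diag(rep$confusion$matched_a)),
         mean(diag(rep$confusion$matched_b))))
}

mean_swapped <- function(rep) {
  mean(c(mean(diag(rep$confusion$swapped_ab)),
         mean(diag(rep$confusion$swapped_ba))))
}

# Brute-force Spearman oracle: explicit midranks + textbook Pearson
# formula, independent of the package implementation.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

dominant_planted_aus <- function(culture) {
  out <- list()
  for (lab in setdiff(EXPRESSIONS, "neutral")) {
    mu <- culture$mean[lab, ]
    out[[lab]] <- names(mu)[mu >= 0.5]
  }
  out
}
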