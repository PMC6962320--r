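# Desk-scale seven-member ensemble, trained once per test session and shared
# by the learning / ensemble-dominance / grad-cam tests. Sizes are chosen so
# the whole build stays in the single-digit minutes on one CPU: 100 phantom
# patches per class, narrow networks (the widths are configurable by design),
# few epochs - the phantom classes are separable by construction, so these
# suffice to demonstrate learning well above chance.

desk_cache <- new.env(parent = emptyenv())

desk_ensemble <- function() {
  if (!is.null(desk_cache$fit)) return(desk_cache$fit)
  seed <- 424242L
  ps <- generate_patchset(100L, mode = "all", seed = seed)
  y <- as.integer(ps$labels)
  idx <- with_seed_local(seed + 1L, {
    lapply(split(seq_along(y), y), function(rows) {
      rows <- sample(rows)
      list(train = rows[1:64], val = rows[65:84], test = rows[85:100])
    })
  })
  tr <- unlist(lapply(idx, `[[`, "train"), use.names = FALSE)
  va <- unlist(lapply(idx, `[[`, "val"), use.names = FALSE)
  norm <- fit_normalization(c(ps$sample_sets$axial2d[tr],
                              ps$sample_sets$axial2d[va]))
  stacks <- lapply(names(ps$sample_sets), function(mode) {
    ss <- lapply(ps$sample_sets[[mode]], apply_normalization, norm)
    roi_stack(ss, needs_context = (mode == "axial2d"))
  })
  names(stacks) <- names(ps$sample_sets)

  fit_one <- function(name) {
    big <- name == "BCNN2D"
    is3d <- grepl("3D$", name)
    spec <- arch_spec(name,
                      filters = if (big) c(8L, 8L, 16L) else c(4L, 4L, 8L),
                      dense_units = if (big) 32L else 16L)
    mode <- spec$input_mode
    x <- stacks[[mode]]$x
    if (!spec$needs_context && mode == "axial2d") x <- x$main
    tr_use <- tr
    # 3D members converge slowly at these tiny widths; a slightly higher
    # learning rate keeps the desk-scale run short
    cfg <- train_config(seed = seed + match(name, arch_names()),
                        batch_size = 64L,
                        lr = if (is3d) 0.003 else 0.001,
                        max_epochs = if (big) 15L else if (is3d) 10L else 12L)
    m <- build_model(spec, cfg)
    m <- train_cnn(m,
                   list(x = slice_batch(x, tr_use), y = y[tr_use]),
                   list(x = slice_batch(x, va), y = y[va]), cfg)
    m$norm_stats <- norm
    val_probs <- t(net_predict_probs_tt(m, slice_batch(x, va)))
    list(model = m, val_probs = val_probs)
  }
  fits <- lapply(arch_names(), fit_one)
  names(fits) <- arch_names()
  desk_cache$fit <- list(
    models = lapply(fits, `[[`, "model"),
    val_probs = lapply(fits, `[[`, "val_probs"),
    y_val = y[va], y = y, idx = list(train = tr, val = va,
                                     test = unlist(lapply(idx, `[[`, "test"),
                                                   use.names = FALSE)),
    norm = norm, patchset = ps, stacks = stacks)
  desk_cache$fit
}

# thin wrappers around internals used by helpers
roi_stack <- function(...) lungtex:::roi_stack(...)
slice_batch <- function(...) lungtex:::slice_batch(...)
with_seed_local <- function(seed, expr) lungtex:::with_seed(seed, expr)
net_predict_probs_tt <- function(m, x) lungtex:::net_predict_probs(m$net, x)
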