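test_that("empty parameters give an all-zero stack and empty ground truth", {
  lay <- test_layout()
  p <- sim_params(nucleus_count = c(negative = 0, cfos_plus = 0,
                                    cfos_plusplus = 0),
                  soma_density = 0, noise_sd = 0)
  sim <- generate_cortex_stack(p, lay)
  expect_equal(sum(vapply(sim$stack$channels, sum, numeric(1))), 0)
  expect_equal(nrow(sim$truth$nuclei), 0L)
  expect_equal(nrow(sim$truth$somata), 0L)
  expect_equal(nrow(sim$truth$branches), 0L)
})

test_that("identical parameters and seed give bit-identical stacks", {
  lay <- test_layout()
  p <- sim_params(nucleus_count = c(negative = 3, cfos_plus = 3,
                                    cfos_plusplus = 3),
                  soma_density = 200, noise_sd = 10, seed = 42)
  a <- generate_cortex_stack(p, lay)
  b <- generate_cortex_stack(p, lay)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
})

test_that("the generator refuses a field too small for the request", {
  lay <- cortex_layout(layer_widths = c("V" = 30), field_size = c(30, 30, 5))
  p <- sim_params(nucleus_count = c(negative = 40, cfos_plus = 0,
                                    cfos_plusplus = 0))
  expect_error(generate_cortex_stack(p, lay), "too small")
})

test_that("ground-truth labels are sound against the rendered stack at zero noise", {
  lay <- test_layout(300, 300)
  for (seed in 1:3) {
    p <- sim_params(nucleus_count = c(negative = 5, cfos_plus = 8,
                                      cfos_plusplus = 8),
                    noise_sd = 0, seed = seed)
    sim <- generate_cortex_stack(p, lay)
    thr <- p$thresholds
    nuc <- sim$truth$nuclei
    act <- nuc[nuc$activation_class != "negative", ]
    strong <- act$area_um2 > thr$min_area & act$mean_gray > thr$min_intensity
    expect_identical(ifelse(strong, "cfos_plusplus", "cfos_plus"),
                     act$activation_class)
    ## re-measure from the rendered stack: detection must reproduce the
    ## recorded area and mean gray of each object
    pr <- project_stack(sim$stack, "max")
    det <- detect_nuclei(pr, channel = "cfos", min_area = 40)
    expect_equal(nrow(det), nrow(act))
    ord_t <- order(act$x_um)
    ord_d <- order(det$x_um)
    expect_equal(det$area_um2[ord_d], act$area_um2[ord_t], tolerance = 1e-8)
    expect_equal(det$mean_gray[ord_d], act$mean_gray[ord_t], tolerance = 1e-6)
  }
})

test_that("every generated nucleus lies inside the field and in its recorded layer", {
  lay <- cortex_layout(layer_widths = c("I" = 60, "II/III" = 60, "V" = 80),
                       field_size = c(200, 150, 8))
  p <- sim_params(nucleus_count = c(negative = 6, cfos_plus = 6,
                                    cfos_plusplus = 6), seed = 11)
  sim <- generate_cortex_stack(p, lay)
  nuc <- sim$truth$nuclei
  expect_true(all(nuc$x_um >= 0 & nuc$x_um <= 200))
  expect_true(all(nuc$y_um >= 0 & nuc$y_um <= 150))
  relabel <- assign_layers(nuc, lay)
  expect_identical(relabel$layer, nuc$layer)
})

test_that("doubling inter-cellular branch density doubles the annulus skeleton content but leaves the single-cell zone unchanged", {
  ## sparse somata so no annulus overlaps another cell's inner disc
  lay <- test_layout(240, 240)
  px_in_zone <- function(sim, lo, hi) {
    pr <- project_stack(sim$stack, "max")
    sk <- skeletonize(binarize(pr$channels$p2y12)$mask)
    so <- sim$truth$somata
    tot <- 0
    idx <- which(sk, arr.ind = TRUE)
    if (!nrow(idx)) return(0)
    xs <- (idx[, 1L] - 0.5) * 0.5
    ys <- (idx[, 2L] - 0.5) * 0.5
    for (s in seq_len(nrow(so))) {
      d <- sqrt((xs - so$x_um[s])^2 + (ys - so$y_um[s])^2)
      tot <- tot + sum(d >= lo & d < hi)
    }
    tot
  }
  inner1 <- inner2 <- outer1 <- outer2 <- numeric(0)
  for (seed in 1:20) {
    base <- sim_params(nucleus_count = c(negative = 0, cfos_plus = 0,
                                         cfos_plusplus = 0),
                       soma_density = 70, intercell_branch_density = 1,
                       seed = seed)
    dbl <- base; dbl$intercell_branch_density <- 2
    s1 <- generate_cortex_stack(base, lay)
    s2 <- generate_cortex_stack(dbl, lay)
    inner1 <- c(inner1, px_in_zone(s1, 0, 20))
    inner2 <- c(inner2, px_in_zone(s2, 0, 20))
    outer1 <- c(outer1, px_in_zone(s1, 20, 40))
    outer2 <- c(outer2, px_in_zone(s2, 20, 40))
  }
  expect_lt(abs(mean(outer2) / mean(outer1) - 2), 0.2)
  expect_lt(abs(mean(inner2) / mean(inner1) - 1), 0.1)
})

test_that("scripted trajectories pass through waypoints with exact arithmetic", {
  ## straight path at 5 cm/s for 600 s -> 3000 cm
  geom <- circle_geometry("open_field", radius = 1600)
  wp <- data.frame(x = c(-1500, 1500), y = c(0, 0))  # a 3000 cm diameter run
  tr <- generate_trajectory("open_field", waypoints = wp, speed = 5,
                            geometry = geom)
  expect_equal(max(tr$t), 600)
  expect_equal(sum(binned_distance(tr, 600)$distance_cm), 3000)
  expect_error(generate_trajectory("open_field",
                                   waypoints = data.frame(x = c(0, 50),
                                                          y = c(0, 0)),
                                   geometry = circle_geometry(radius = 20)),
               "outside")
})

test_that("random-walk trajectories are deterministic under a fixed seed and stay in the arena", {
  a <- generate_trajectory("open_field", duration = 30, seed = 5)
  b <- generate_trajectory("open_field", duration = 30, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(sqrt(a$x^2 + a$y^2) <= 20 + 1e-6))
  expect_true(all(diff(a$t) > 0))
  ym <- generate_trajectory("ymaze", duration = 30, seed = 2)
  g <- attr(ym, "geometry")
  expect_true(all(point_in_arena(ym$x, ym$y, g)))
})

test_that("the release simulator conserves radioactivity and honours its arithmetic", {
  s <- generate_release_series(basal_fraction = 1, stim_gain = 1,
                               n_samples = 1, stim_sample_index = 1,
                               tissue_initial = 1000)
  expect_equal(s$released, 10)
  expect_equal(s$tissue_after, 990)
  for (bf in c(0.5, 1, 5)) for (g in c(1, 2, 4)) {
    s <- generate_release_series(basal_fraction = bf, stim_gain = g,
                                 n_samples = 12, stim_sample_index = 5,
                                 tissue_initial = 3.7e4)
    expect_equal(sum(s$released) + s$tissue_after, 3.7e4,
                 tolerance = 1e-9)
  }
  expect_error(generate_release_series(basal_fraction = 50, stim_gain = 3,
                                       n_samples = 5, stim_sample_index = 2),
               "negative tissue pool")
  expect_error(generate_release_series(basal_fraction = 0), "between 0 and 100")
})

test_that("simulation parameter configs round-trip through YAML", {
  p <- sim_params(noise_sd = 12.5, soma_density = 333,
                  intercell_branch_density = 1.3, seed = 99)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(p, path)
  q <- read_sim_config(path)
  expect_equal(unclass(q)[names(unclass(p))], unclass(p), tolerance = 1e-12)
})

test_that("image stacks round-trip through TIFF with sidecar metadata", {
  lay <- test_layout(60, 60, 4)
  p <- sim_params(nucleus_count = c(negative = 1, cfos_plus = 1,
                                    cfos_plusplus = 1), seed = 3)
  sim <- generate_cortex_stack(p, lay)
  path <- tempfile(fileext = ".tif")
  write_stack(sim$stack, path)
  back <- read_stack(path)
  expect_equal(names(back$channels), names(sim$stack$channels))
  expect_equal(back$voxel_size, sim$stack$voxel_size)
  expect_equal(back$channels$cfos, sim$stack$channels$cfos,
               tolerance = 1e-5)
})
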