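test_that("initial dot count follows density times angular screen area", {
  cam <- default_cam
  # frozen from the product-of-extents formula:
  # 2*atan(1.12) = 96.4794 deg, 2*atan(0.925) = 85.5377 deg,
  # product 8252.62 deg^2, times 1.4694 dots/deg^2
  expect_equal(round(1.4694 * screen_angular_area(cam, "product")), 12126)
  cfg <- stimulus_config(seed = 3)
  fld <- init_dot_field(cfg)
  expect_equal(length(fld$x), 12126L)
  # solid-angle convention is smaller and consistent with its own formula
  cfg2 <- stimulus_config(seed = 3, area_convention = "solid_angle")
  expect_equal(length(init_dot_field(cfg2)$x),
               round(1.4694 * screen_angular_area(cam, "solid_angle")))
  expect_lt(screen_angular_area(cam, "solid_angle"),
            screen_angular_area(cam, "product"))
  # zero density gives an empty field
  expect_equal(length(init_dot_field(stimulus_config(density = 0))$x), 0L)
})

test_that("stimulus generation is deterministic per seed and distinct across seeds", {
  a <- generate_stimulus(quick_config(seed = 5))
  b <- generate_stimulus(quick_config(seed = 5))
  c <- generate_stimulus(quick_config(seed = 6))
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames[[50]]$x, c$frames[[50]]$x))
})

test_that("a 1.7-s stimulus at 60 Hz has 102 frames spanning 1.5 gait cycles", {
  cfg <- quick_config(seed = 1)
  stim <- generate_stimulus(cfg)
  expect_equal(stim$n_frames, 102L)
  expect_equal(cfg$duration * cfg$camera$frame_rate, 102)
  expect_equal(cfg$duration / shared_gait$period, 1.5)
  expect_error(stimulus_config(duration = 1.71), "integer number of frames")
})

test_that("limited lifetime replaces the expected fraction of dots", {
  # near-zero observer speed isolates lifetime replacement from respawn
  cfg <- stimulus_config(observer = observer_motion(0, 1e-9),
                         density = 1.4694, seed = 8)
  stim <- generate_stimulus(cfg)
  fresh <- sapply(stim$frames[-1], function(f) mean(f$fresh))
  n <- nrow(stim$frames[[1]])
  se <- sqrt(0.15 * 0.85 / (n * length(fresh)))
  expect_lt(abs(mean(fresh) - 0.15), 4 * se)
})

test_that("with no walker the engine reduces to the pure ground-plane flow field", {
  cfg <- quick_config(seed = 2, density = 1.4694)
  stim <- generate_stimulus(cfg)
  co <- stimulus_correspondences(stim)
  co <- co[co$frame == 60, ]
  d <- background_flow(cbind(co$x, co$y), cfg$observer, cfg$camera,
                       1 / cfg$camera$frame_rate)
  expect_equal(co$dx, unname(d[, 1]), tolerance = 1e-12)
  expect_equal(co$dy, unname(d[, 2]), tolerance = 1e-12)
})

test_that("labels are diagnostic only and can be dropped", {
  a <- generate_stimulus(quick_config("incongruent_with_walker", seed = 4),
                         gait = shared_gait, labels = TRUE)
  b <- generate_stimulus(quick_config("incongruent_with_walker", seed = 4),
                         gait = shared_gait, labels = FALSE)
  expect_named(b$frames[[10]], c("frame", "id", "x", "y", "fresh"))
  expect_true("label" %in% names(a$frames[[10]]))
  a$frames <- lapply(a$frames, function(f) f[names(f) != "label"])
  expect_identical(a$frames, b$frames)
})

test_that("incongruent inside dots move with the walker's negated lateral velocity", {
  cfg <- stimulus_config(path = walker_path("equidistant", "right"),
                         condition = "incongruent_with_walker",
                         density = 1.4694, seed = 9)
  cam <- cfg$camera
  dt <- 1 / cam$frame_rate
  stim <- generate_stimulus(cfg, gait = shared_gait)
  i <- 40
  st <- walker_state_at(cfg$path, shared_gait, i * dt, observer = cfg$observer)
  f1 <- stim$frames[[i]]
  f2 <- stim$frames[[i + 1]]
  ins <- f1$label == "walker"
  expect_gt(sum(ins), 5)
  k <- match(f1$id[ins], f2$id)
  ok <- !is.na(k) & !f2$fresh[pmax(k, 1L)]
  # recover the world-lateral velocity at the walker plane
  zw <- st$body_center[3]
  vx <- (f2$x[k[ok]] - f1$x[ins][ok]) * zw / (cam$viewing_distance * dt)
  # walker translates at +1.2 m/s; inside dots at exactly -1.2 m/s
  expect_true(all(abs(vx - (-1.2)) < 1e-9))
  vy <- (f2$y[k[ok]] - f1$y[ins][ok]) * zw / (cam$viewing_distance * dt)
  expect_true(all(abs(vy) < 1e-9))
})

test_that("congruent-with-flow dots move along the background direction, faster", {
  cfg <- stimulus_config(path = walker_path("equidistant", "right"),
                         condition = "congruent_with_flow",
                         density = 1.4694, seed = 10)
  cam <- cfg$camera
  dt <- 1 / cam$frame_rate
  stim <- generate_stimulus(cfg, gait = shared_gait)
  for (i in c(20, 60, 90)) {
    f1 <- stim$frames[[i]]
    f2 <- stim$frames[[i + 1]]
    ins <- f1$label == "walker" & f1$y < 0
    k <- match(f1$id[ins], f2$id)
    ok <- !is.na(k) & !f2$fresh[pmax(k, 1L)]
    dx <- f2$x[k[ok]] - f1$x[ins][ok]
    dy <- f2$y[k[ok]] - f1$y[ins][ok]
    bg <- background_flow(cbind(f1$x[ins][ok], f1$y[ins][ok]),
                          cfg$observer, cam, dt)
    # same direction (collinear, same sense) ...
    cross <- dx * bg[, 2] - dy * bg[, 1]
    dot <- dx * bg[, 1] + dy * bg[, 2]
    expect_true(all(abs(cross) < 1e-10))
    expect_true(all(dot > 0))
    # ... but at least the background speed (walker closer than the plane)
    expect_true(all(dx^2 + dy^2 >= rowSums(bg^2) - 1e-14))
  }
})

test_that("congruent-with-flow moves sky-region dots that the background leaves static", {
  # a tall synthetic gait raises the head disk above the horizon
  tall <- synthesize_gait(gait_params(heights = c(
    head = 2.1, shoulder = 1.45, elbow = 1.18, wrist = 0.95, hand = 0.86,
    hip = 0.95, knee = 0.52, ankle = 0.12, foot = 0.04, pelvis = 0.98)))
  cfg <- stimulus_config(path = walker_path("equidistant", "right"),
                         condition = "congruent_with_flow",
                         density = 1.4694, seed = 11)
  stim <- generate_stimulus(cfg, gait = tall)
  co <- NULL
  for (i in c(30, 50, 70)) {
    f1 <- stim$frames[[i]]
    f2 <- stim$frames[[i + 1]]
    ins <- f1$label == "walker" & f1$y > 0.005
    if (!any(ins)) next
    k <- match(f1$id[ins], f2$id)
    ok <- !is.na(k) & !f2$fresh[pmax(k, 1L)]
    co <- rbind(co, cbind(f2$x[k[ok]] - f1$x[ins][ok],
                          f2$y[k[ok]] - f1$y[ins][ok]))
  }
  expect_gt(nrow(co), 0)
  expect_true(all(rowSums(co^2) > 0))
})

test_that("dots exiting the silhouette are captured by the background flow", {
  cfg <- stimulus_config(path = walker_path("equidistant", "right"),
                         condition = "incongruent_with_walker",
                         density = 1.4694, seed = 12)
  cam <- cfg$camera
  dt <- 1 / cam$frame_rate
  stim <- generate_stimulus(cfg, gait = shared_gait)
  checked <- 0L
  for (i in 30:60) {
    f1 <- stim$frames[[i]]
    f2 <- stim$frames[[i + 1]]
    # walker at frame i, background at frame i+1, still tracked at i+2
    exiting <- f1$id[f1$label == "walker"]
    k2 <- match(exiting, f2$id)
    sel <- !is.na(k2) & f2$label[pmax(k2, 1L)] == "background" &
      !f2$fresh[pmax(k2, 1L)]
    ids <- exiting[sel]
    if (!length(ids)) next
    f3 <- stim$frames[[i + 2]]
    k2 <- match(ids, f2$id)
    k3 <- match(ids, f3$id)
    ok <- !is.na(k3) & !f3$fresh[pmax(k3, 1L)]
    if (!any(ok)) next
    d_obs <- cbind(f3$x[k3[ok]] - f2$x[k2[ok]], f3$y[k3[ok]] - f2$y[k2[ok]])
    d_bg <- background_flow(cbind(f2$x[k2[ok]], f2$y[k2[ok]]),
                            cfg$observer, cam, dt)
    expect_equal(unname(d_obs), unname(d_bg), tolerance = 1e-12)
    checked <- checked + sum(ok)
  }
  expect_gt(checked, 10)
})

test_that("congruent-with-walker seeds disk dots and occludes covered background", {
  cfg <- stimulus_config(path = walker_path("equidistant", "right"),
                         condition = "congruent_with_walker",
                         density = 1.4694, seed = 13)
  cam <- cfg$camera
  stim <- generate_stimulus(cfg, gait = shared_gait)
  f <- stim$frames[[50]]
  st <- walker_state_at(cfg$path, shared_gait, 50 / 60, observer = cfg$observer)
  mem <- body_membership(cbind(f$x, f$y), st, cam)
  # every visible dot inside the silhouette is a walker (disk) dot
  expect_true(all(f$label[mem$inside] == "walker"))
  # disk dots ride their joints: their count is stable and positive
  nw <- sapply(stim$frames, function(fr) sum(fr$label == "walker"))
  expect_true(all(nw > 10))
})

test_that("frames rasterize to the display resolution with one pixel per dot", {
  cfg <- quick_config(seed = 14, density = 0.05)
  stim <- generate_stimulus(cfg)
  dir <- withr::local_tempdir()
  paths <- render_frames(stim, dir)
  expect_length(paths, 102L)
  img <- png::readPNG(paths[1])
  expect_equal(dim(img), c(600L, 800L))
  expect_lte(sum(img > 0), nrow(stim$frames[[1]]))

  # a dot at the screen centre lights the central pixel neighbourhood
  centre <- structure(list(
    config = cfg,
    frames = list(data.frame(frame = 1, id = 1L, x = 0, y = 0,
                             fresh = FALSE)),
    n_frames = 1L), class = "fw_stimulus")
  p <- render_frames(centre, dir, prefix = "centre")
  img <- png::readPNG(p[1])
  w <- which(img > 0, arr.ind = TRUE)
  expect_equal(nrow(w), 1L)
  expect_lte(max(abs(w - c(300, 400))), 1)

  # an empty frame is all black
  empty <- centre
  empty$frames[[1]] <- empty$frames[[1]][0, ]
  p <- render_frames(empty, dir, prefix = "empty")
  expect_true(all(png::readPNG(p[1]) == 0))
})

test_that("stimulus configs round-trip through YAML", {
  cfg <- stimulus_config(observer = observer_motion(-5),
                         path = walker_path("approaching", "left"),
                         condition = "congruent_with_flow",
                         articulation = "backward", translation = "moonwalk",
                         seed = 77)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_stimulus_config(cfg, f)
  cfg2 <- read_stimulus_config(f)
  expect_equal(cfg2, cfg)
})
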