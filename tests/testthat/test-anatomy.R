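test_that("the packaged default geometry parses and validates", {
  geom <- load_geometry()
  expect_s3_class(geom, "msk_geometry")
  expect_length(geom$muscles, 18)
  expect_length(geom$ligaments, 4)
  expect_length(geom$contacts, 3)
  expect_true(all(vapply(geom$muscles, `[[`, numeric(1), "f_max") > 0))
  expect_true(all(vapply(geom$ligaments, `[[`, numeric(1), "l_max") > 0))
  # right-limb convention: medial contact more medial than lateral
  expect_lt(unlist(geom$contacts$medial$xyz)[3],
            unlist(geom$contacts$lateral$xyz)[3])
})

test_that("geometry validation rejects malformed files", {
  g <- yaml::read_yaml(default_geometry_path())
  g$muscles[[1]]$pcsa <- 0
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(g, bad)
  expect_error(load_geometry(bad), "positive")

  g2 <- yaml::read_yaml(default_geometry_path())
  g2$muscles[[2]]$attachments[[1]]$segment <- "femur_typo"
  yaml::write_yaml(g2, bad)
  expect_error(load_geometry(bad), "undefined segment")
})

test_that("geometry survives a write/read round trip", {
  geom <- load_geometry()
  tmp <- tempfile(fileext = ".yaml")
  write_geometry(geom, tmp)
  geom2 <- load_geometry(tmp)
  expect_equal(length(geom2$muscles), length(geom$muscles))
  for (i in seq_along(geom$muscles)) {
    expect_equal(unlist(geom2$muscles[[i]]$attachments[[1]]$xyz),
                 unlist(geom$muscles[[i]]$attachments[[1]]$xyz),
                 tolerance = 1e-9)
    expect_equal(geom2$muscles[[i]]$f_max, geom$muscles[[i]]$f_max,
                 tolerance = 1e-9)
  }
  expect_equal(unlist(geom2$contacts$medial$xyz),
               unlist(geom$contacts$medial$xyz), tolerance = 1e-9)
})

test_that("maximum muscle force is stress times area", {
  expect_equal(f_max_from_pcsa(10, 31.39), 313.9)
  expect_gt(f_max_from_pcsa(1e-4, 31.39), 0)
  expect_error(f_max_from_pcsa(10, 0), "positive")
  expect_error(f_max_from_pcsa(-1), "positive")
})

test_that("rho lookup interpolates and clamps", {
  geom <- load_geometry()
  lk <- geom$rho_lookup
  expect_equal(rho_at(geom, lk$flexion_deg[1]), lk$ratio[1])
  mid <- (lk$flexion_deg[1] + lk$flexion_deg[2]) / 2
  expect_equal(rho_at(geom, mid), (lk$ratio[1] + lk$ratio[2]) / 2)
  expect_equal(rho_at(geom, 1e4), lk$ratio[length(lk$ratio)])
})

test_that("lines of action point along the path with unit ends", {
  poses <- list(shank = neutral_pose(c(0, 0, 0.42)),
                foot = neutral_pose(c(0, 0, 0)))
  # straight vertical two-point path
  att <- list(list(segment = "shank", xyz = c(0, -0.1, 0)),
              list(segment = "foot", xyz = c(0, 0.05, 0)))
  ct <- line_of_action(att, poses)
  expect_length(ct, 2)
  expect_equal(sqrt(sum(ct[[1]]$p_hat^2)), 1, tolerance = 1e-12)
  expect_equal(ct[[1]]$p_hat, -ct[[2]]$p_hat, tolerance = 1e-12)

  # via point at a right angle: each end aims at the via, not the far end
  att3 <- list(list(segment = "shank", xyz = c(0, -0.1, 0)),
               list(segment = "shank", xyz = c(0.1, -0.2, 0)),
               list(segment = "foot", xyz = c(0.1, 0.1, 0)))
  ct3 <- line_of_action(att3, poses)
  origin_pt <- ct3[[1]]$point; via_pt <- ct3[[2]]$point; ins_pt <- ct3[[3]]$point
  expect_equal(ct3[[3]]$p_hat,
               (via_pt - ins_pt) / sqrt(sum((via_pt - ins_pt)^2)),
               tolerance = 1e-12)
  expect_equal(ct3[[1]]$p_hat,
               (via_pt - origin_pt) / sqrt(sum((via_pt - origin_pt)^2)),
               tolerance = 1e-12)

  expect_error(line_of_action(list(
    list(segment = "shank", xyz = c(0, -0.1, 0)),
    list(segment = "shank", xyz = c(0, -0.1, 0))), poses), "coincident")
})

test_that("lever and direction vectors are frame-equivariant", {
  R <- rot_axis_angle_test(c(1, 2, 3), 0.8)
  shift <- c(0.4, -0.7, 1.2)
  poses <- list(shank = neutral_pose(c(0, 0, 0.42)),
                foot = neutral_pose(c(0, 0, 0)))
  posesR <- lapply(poses, function(p) {
    segment_pose(R %*% p$rotation, as.numeric(R %*% p$origin) + shift)
  })
  att <- list(list(segment = "shank", xyz = c(0.02, -0.1, 0.01)),
              list(segment = "foot", xyz = c(-0.05, -0.06, 0)))
  a <- line_of_action(att, poses)
  b <- line_of_action(att, posesR)
  for (i in 1:2) {
    expect_equal(b[[i]]$p_hat, as.numeric(R %*% a[[i]]$p_hat), tolerance = 1e-12)
    expect_equal(b[[i]]$r_vec, as.numeric(R %*% a[[i]]$r_vec), tolerance = 1e-12)
  }
})

test_that("unit-force joint moments match a virtual-work oracle", {
  # moment of a unit muscle force about the proximal joint = r x p;
  # oracle: numerical derivative of muscle length wrt a small joint rotation
  poses <- list(shank = neutral_pose(c(0, 0, 0.42)),
                foot = neutral_pose(c(0, 0, 0)))
  att <- list(list(segment = "shank", xyz = c(-0.02, -0.1, 0)),
              list(segment = "foot", xyz = c(-0.05, -0.06, 0)))
  ct <- line_of_action(att, poses)
  foot_ct <- ct[[2]]
  m_foot <- cross3_test(foot_ct$r_vec, foot_ct$p_hat)

  len <- function(poses) {
    p1 <- pose_transform(poses$shank, unlist(att[[1]]$xyz))
    p2 <- pose_transform(poses$foot, unlist(att[[2]]$xyz))
    sqrt(sum((p1 - p2)^2))
  }
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    h <- 1e-7
    rot_foot <- function(s) {
      p <- poses
      Rh <- rot_axis_angle_test(ax, s)
      p$foot <- segment_pose(Rh %*% p$foot$rotation, p$foot$origin)
      p
    }
    dldtheta <- (len(rot_foot(h)) - len(rot_foot(-h))) / (2 * h)
    # virtual work: rotating the foot shortens the path at rate m . axis
    expect_equal(-sum(m_foot * ax), dldtheta, tolerance = 1e-5)
  }
})

test_that("geometry scaling rescales coordinates and strength", {
  geom <- load_geometry()
  lengths <- list(thigh = 0.21, shank = 0.42, foot = 0.25, pelvis = 0.20,
                  patella = 0.04)
  g2 <- scale_geometry(geom, lengths)
  # thigh-local coordinates halve (reference length 0.42)
  i <- which(vapply(geom$muscles, `[[`, character(1), "name") ==
               "vastus_lateralis")
  expect_equal(unlist(g2$muscles[[i]]$attachments[[1]]$xyz),
               unlist(geom$muscles[[i]]$attachments[[1]]$xyz) * 0.5,
               tolerance = 1e-12)
  g3 <- scale_geometry(geom, lengths, mass = 140)
  expect_equal(g3$muscles[[1]]$f_max / geom$muscles[[1]]$f_max, 2^(2 / 3),
               tolerance = 1e-12)
})
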