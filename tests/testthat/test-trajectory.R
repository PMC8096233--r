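test_that("equilibration trimming drops the leading floor(fraction * N) frames", {
  tr <- makeTraj(array(seq_len(10 * 2 * 3), c(10, 2, 3)))
  expect_identical(coords(trimEquilibration(tr, 0)), coords(tr))
  expect_equal(nFrames(trimEquilibration(tr, 0.45)), 6)  # floor rule
  tr250 <- makeTraj(array(0, c(250, 2, 3)))
  expect_equal(nFrames(trimEquilibration(tr250, 0.4)), 150)
  expect_error(trimEquilibration(tr, 1), "fraction")
  # frames kept are the last ones
  out <- trimEquilibration(tr, 0.2)
  expect_equal(coords(out)[1, , ], coords(tr)[3, , ])
})

test_that("superposition removes rigid motion and rejects mirror images", {
  set.seed(41)
  ref <- matrix(rnorm(30), 10, 3)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  x <- array(NA_real_, c(2, 10, 3))
  x[1, , ] <- ref
  x[2, , ] <- ref %*% R + matrix(c(3, -1, 7), 10, 3, byrow = TRUE)
  tr <- makeTraj(x)
  al <- superposeTrajectory(tr)
  expect_lt(max(al$rmsd), 1e-8)
  # mirror image cannot be superposed by a proper rotation
  xm <- x
  xm[2, , ] <- ref %*% diag(c(-1, 1, 1))
  alm <- superposeTrajectory(makeTraj(xm))
  expect_gt(max(alm$rmsd), 0.1)
  # collinear selections are a geometry error
  line <- array(rep(cbind(1:5, 0, 0), each = 2), c(2, 5, 3))
  expect_error(superposeTrajectory(makeTraj(line)), "collinear")
  # cross-check the optimal fit against an independent implementation
  fit <- h3tails:::kabsch(x[2, , ], ref)
  b3 <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(ref)),
                                        mobile = as.vector(t(x[2, , ]))))
  expect_equal(as.vector(t(h3tails:::applyKabsch(x[2, , ], fit))),
               as.vector(b3), tolerance = 1e-6)
})

test_that("RMSF recovers planted isotropic fluctuations and replicate SEM", {
  # static trajectory: RMSF identically zero
  tr0 <- staticTraj(matrix(rnorm(15), 5, 3), nFrames = 3)
  expect_equal(rmsfProfile(list(tr0), selection = 1:5)$rmsf, rep(0, 5))
  # isotropic sigma = 1 per axis: RMSF -> sqrt(3)
  set.seed(42)
  x <- array(rnorm(5000 * 4 * 3), c(5000, 4, 3))
  rp <- rmsfProfile(list(makeTraj(x)), selection = 1:4)
  expect_equal(rp$rmsf, rep(sqrt(3), 4), tolerance = 0.03)
  # across-replicate mean and SEM from two replicates
  mk <- function(s) makeTraj(array(rnorm(4000 * 1 * 3, 0, s), c(4000, 1, 3)))
  prof <- rmsfProfile(list(mk(2 / sqrt(3)), mk(4 / sqrt(3))), selection = 1)
  expect_equal(prof$rmsf, mean(c(prof$rep1, prof$rep2)))
  expect_equal(prof$sem, sd(c(prof$rep1, prof$rep2)) / sqrt(2))
  expect_error(rmsfProfile(list(makeTraj(array(0, c(1, 2, 3))))), "2 frames")
})

test_that("RMSF of AR(1) tails matches sqrt(3) sigma and survives rigid-body motion", {
  sp <- toyParticleSpec("nucleosome", sigmaTailA = 1.2, sigmaTailE = 1.2,
                        rho = 0, coreJitterSd = 0, nFrames = 5000, seed = 13)
  tr <- simulateParticleTrajectory(sp)
  sel <- selectAtoms(tr, role = "tail", chain = "A")
  base <- rmsfProfile(list(tr), selection = sel)$rmsf
  expect_equal(base, rep(sqrt(3) * 1.2, 37), tolerance = 0.05)
  # apply a global rigid-body motion per frame, then superpose on the core
  x <- coords(tr)
  th <- seq(0, 1, length.out = nFrames(tr))
  for (f in seq_len(nFrames(tr))) {
    R <- matrix(c(cos(th[f]), -sin(th[f]), 0,
                  sin(th[f]), cos(th[f]), 0, 0, 0, 1), 3, 3)
    x[f, , ] <- x[f, , ] %*% R + matrix(c(10, 0, -5) * th[f],
                                        nAtoms(tr), 3, byrow = TRUE)
  }
  moved <- new("TailTrajectory", coords = x, topology = topology(tr),
               dtPs = 10)
  al <- superposeTrajectory(moved, selectAtoms(tr, role = "core"))
  after <- rmsfProfile(list(al$trajectory), selection = sel)$rmsf
  expect_equal(after, base, tolerance = 0.02)
})

test_that("RAC equals mean RMSD at tau = 1, 0 at tau = N, and decays for AR(1)", {
  # constant trajectory: RAC identically zero
  trC <- staticTraj(matrix(rnorm(9), 3, 3), nFrames = 6)
  expect_equal(racCurve(trC, c(1, 3, 6))$rac, rep(0, 3))
  sp <- toyParticleSpec("nucleosome", rho = 0.9, coreJitterSd = 0,
                        nFrames = 400, seed = 17)
  tr <- simulateParticleTrajectory(sp)
  sel <- selectAtoms(tr, role = "tail")
  rc <- racCurve(tr, tauGrid = c(1, 10, 50, 100, 200, 400), selection = sel)
  # tau = 1: mean per-frame RMSD to the average structure
  x <- coords(tr)[, sel, , drop = FALSE]
  avg <- apply(x, c(2, 3), mean)
  manual <- mean(vapply(seq_len(dim(x)[1]), function(f)
    sqrt(mean(rowSums((x[f, , ] - avg)^2))), numeric(1)))
  expect_equal(rc$rac[1], manual, tolerance = 1e-10)
  expect_equal(rc$rac[rc$tau == 400], 0, tolerance = 1e-10)
  expect_true(all(diff(rc$rac) <= 1e-10))
  expect_error(racCurve(tr, tauGrid = 1000), "tau")
})

test_that("radius of gyration matches hand geometry and is rotation invariant", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0))
  tr <- staticTraj(xyz, nFrames = 1)
  expect_equal(radiusOfGyration(tr), 1.0)
  trSame <- staticTraj(matrix(5, 3, 3), nFrames = 2)
  expect_equal(radiusOfGyration(trSame), c(0, 0))
  set.seed(3)
  pts <- matrix(rnorm(30), 10, 3)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  x <- array(NA_real_, c(2, 10, 3))
  x[1, , ] <- pts
  x[2, , ] <- pts %*% R + 3
  rg <- radiusOfGyration(makeTraj(x))
  expect_equal(rg[1], rg[2], tolerance = 1e-12)
  expect_error(radiusOfGyration(tr, integer()), "empty")
})

test_that("Shrake-Rupley areas match sphere geometry", {
  # isolated sphere r = 1.7 + probe 1.4: area 4 pi 3.1^2
  a1 <- sasa(matrix(0, 1, 3), radii = 1.7, nPoints = 960)
  expect_equal(a1[[1]], 4 * pi * 3.1^2, tolerance = 0.01 * 4 * pi * 3.1^2)
  # convergence: within 0.5% at 4000 points
  a4k <- sasa(matrix(0, 1, 3), radii = 1.7, nPoints = 4000)
  expect_equal(a4k[[1]], 4 * pi * 3.1^2, tolerance = 0.005 * 4 * pi * 3.1^2)
  # two distant atoms: additivity
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  a2 <- sasa(xyz, radii = c(1.7, 1.5), nPoints = 960)
  expect_equal(attr(a2, "total"),
               4 * pi * (1.7 + 1.4)^2 + 4 * pi * (1.5 + 1.4)^2,
               tolerance = 1e-9)
  # an atom enclosed by a tight shell is fully buried
  sph <- 2.0 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1),
                     cbind(c(1, 1, 1, 1, -1, -1, -1, -1) / sqrt(3),
                           c(1, 1, -1, -1, 1, 1, -1, -1) / sqrt(3),
                           c(1, -1, 1, -1, 1, -1, 1, -1) / sqrt(3)))
  buried <- sasa(rbind(c(0, 0, 0), sph),
                 radii = c(1.0, rep(2.5, nrow(sph))), nPoints = 960,
                 selection = 1)
  expect_lt(buried[[1]], 1e-9)
  expect_error(sasa(matrix(0, 1, 3), radii = c(C = 1.7), elements = "Zz"),
               "Zz")
})

test_that("contact counting is inclusive at the cutoff and matches brute force", {
  mkPair <- function(d) {
    x <- array(NA_real_, c(2, 2, 3))
    x[, 1, ] <- 0
    x[, 2, ] <- matrix(c(d, 0, 0), 2, 3, byrow = TRUE)
    topo <- data.frame(chain = c("A", "I"), resno = c(1, 50),
                       resname = c("GLY", "DA"), atom = c("CA", "P"),
                       heavy = TRUE, role = c("tail", "DNA"))
    new("TailTrajectory", coords = x, topology = topo, dtPs = 10)
  }
  expect_equal(contactCounts(contactMatrix(mkPair(4.4)))[1, 1], 1.0)
  expect_equal(contactCounts(contactMatrix(mkPair(4.6)))[1, 1], 0.0)
  # half-frame contact: count k/2
  x <- array(NA_real_, c(2, 2, 3))
  x[, 1, ] <- 0
  x[1, 2, ] <- c(4.0, 0, 0)
  x[2, 2, ] <- c(9.0, 0, 0)
  tr <- mkPair(4)
  tr@coords <- x
  expect_equal(contactCounts(contactMatrix(tr))[1, 1], 0.5)
  # random geometries: vectorised counting equals the all-pairs oracle
  set.seed(51)
  for (i in 1:5) {
    sp <- toyParticleSpec("hexasome", nFrames = 3, seed = i)
    trr <- simulateParticleTrajectory(sp)
    cm <- contactMatrix(trr, chain = "A")
    bf <- h3tails:::contactMatrixBruteForce(trr, chain = "A")
    expect_equal(contactCounts(cm), bf, tolerance = 1e-12)
  }
})

test_that("superhelical locations map base pairs onto half-integer bins", {
  expect_equal(shlAssign(74), 0.0)      # dyad
  expect_equal(shlAssign(4), -7.0)      # (4 - 74) / 10
  expect_equal(shlAssign(147), 7.0)     # 7.3 clamped to the SHL 7 edge
  expect_equal(shlAssign(1), -7.0)      # clamped low end
  expect_equal(shlAssign(77), 0.5)      # 0.3 rounds half-up to 0.5
  expect_equal(shlAssign(76), 0.0)      # 0.2 rounds down
  expect_error(shlAssign(0), "range")
  expect_error(shlAssign(148), "range")
  # monotone over the full particle
  expect_true(all(diff(shlAssign(1:147)) >= 0))
})

test_that("contact profiles sum correctly into SHL bins", {
  counts <- matrix(0, 2, 147, dimnames = list(1:2, 1:147))
  counts[1, 74] <- 2    # SHL 0
  counts[2, 74] <- 1    # SHL 0
  counts[1, 4] <- 3     # SHL -7
  counts[2, 147] <- 5   # clamps to SHL 7
  cm <- new("ContactMatrix", counts = counts, cutoff = 4.5,
            framesUsed = 10L, chain = "A")
  prof <- contactsByShl(cm)
  expect_equal(prof$contacts[prof$shl == 0], 3)
  expect_equal(prof$contacts[prof$shl == -7], 3)
  expect_equal(prof$contacts[prof$shl == 7], 5)
  expect_equal(sum(prof$contacts), sum(counts))
  expect_equal(totalContacts(cm), 11)
})

test_that("inter-residue distance maps report chain geometry and compactness", {
  # straight chain, 3.8 A spacing: d(i, j) = 3.8 |i - j|
  n <- 12
  xyz <- cbind(3.8 * seq_len(n), 0, 0)
  tr <- staticTraj(xyz, nFrames = 2)
  dm <- interResidueDistances(tr, seq_len(n))
  expect_equal(unname(dm[1, n]), 3.8 * (n - 1), tolerance = 1e-12)
  expect_true(isSymmetric(unclass(dm)))
  expect_equal(unname(diag(dm)), rep(0, n))
  # collapsed ensemble has smaller long-range compactness than extended
  spExt <- toyParticleSpec("nucleosome", sigmaTailA = 0.5, sigmaTailE = 0.5,
                           nFrames = 50, seed = 5)
  trExt <- simulateParticleTrajectory(spExt)
  sel <- selectAtoms(trExt, role = "tail", chain = "A")
  dExt <- attr(interResidueDistances(trExt, sel), "compactness")
  xs <- coords(trExt)
  collapsed <- xs * 0.3  # uniform shrink of every frame
  trCol <- new("TailTrajectory", coords = collapsed,
               topology = topology(trExt), dtPs = 10)
  dCol <- attr(interResidueDistances(trCol, sel), "compactness")
  expect_lt(dCol, dExt)
  expect_error(interResidueDistances(trExt, sel[1]), "2 residues")
})

test_that("histogram KLD matches the Gaussian closed form and is non-negative", {
  set.seed(61)
  a <- matrix(rnorm(1e5, 0, 20), ncol = 1)
  b <- matrix(rnorm(1e5, 60, 20), ncol = 1)
  closed <- log(20 / 20) + (20^2 + 60^2) / (2 * 20^2) - 0.5  # 4.5 nats
  est <- dihedralKld(a, b)$kld
  expect_equal(est, closed, tolerance = 0.10 * closed)
  expect_equal(dihedralKld(a, a)$kld, 0, tolerance = 1e-12)
  # non-negativity over random inputs
  for (i in 1:20) {
    x <- matrix(rnorm(200, rnorm(1, 0, 40), runif(1, 5, 60)), ncol = 1)
    y <- matrix(rnorm(200, rnorm(1, 0, 40), runif(1, 5, 60)), ncol = 1)
    expect_gte(dihedralKld(x, y)$kld, 0)
  }
  # estimator bias shrinks with sample size
  bias <- vapply(c(1e3, 1e4, 1e5), function(n) {
    xa <- matrix(rnorm(n, 0, 20), ncol = 1)
    xb <- matrix(rnorm(n, 60, 20), ncol = 1)
    abs(dihedralKld(xa, xb)$kld - closed)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("KLD permutation test separates planted shifts from replicate noise", {
  set.seed(62)
  mkReps <- function(mu) lapply(1:4, function(i)
    matrix(rnorm(500, mu, 20), ncol = 1))
  shifted <- dihedralKld(mkReps(0), mkReps(60), nPerm = 200, seed = 1)
  expect_lt(shifted$p.value, 0.05)
  null <- dihedralKld(mkReps(0), mkReps(0), nPerm = 200, seed = 1)
  expect_gt(null$p.value, 0.1)
})

test_that("pseudo-dihedrals recover planar and helical geometry", {
  # four points in a plane with a trans arrangement: 180 degrees
  z <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  tr <- staticTraj(z, nFrames = 1)
  d <- pseudoDihedrals(tr, 1:4)
  expect_equal(abs(d[1, 1]), 180, tolerance = 1e-9)
  # cis arrangement: 0 degrees
  zc <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(pseudoDihedrals(staticTraj(zc, nFrames = 1), 1:4)[1, 1], 0,
               tolerance = 1e-9)
  expect_error(pseudoDihedrals(tr, 1:3), "4 beads")
})

test_that("tail PCA recovers a planted one-dimensional mode with the sign convention", {
  sp <- toyParticleSpec("nucleosome", nFrames = 200, seed = 7)
  tr <- simulateParticleTrajectory(sp)
  sel <- selectAtoms(tr, role = "tail", chain = "A")
  mean3 <- apply(coords(tr)[, sel, , drop = FALSE], c(2, 3), mean)
  set.seed(71)
  mode <- rnorm(length(sel) * 3)
  mode <- mode / sqrt(sum(mode^2))
  amp <- rnorm(200, 0, 5)
  x <- coords(tr)
  x[, sel, ] <- array(rep(mean3, each = 200), c(200, length(sel), 3)) +
    array(matrix(mode, 200, length(sel) * 3, byrow = TRUE) * amp,
          c(200, length(sel), 3))
  planted <- new("TailTrajectory", coords = x, topology = topology(tr),
                 dtPs = 10)
  p <- pcaTails(list(planted = planted), selection = sel)
  expect_gte(p$varianceFraction[1], 0.95)
  # eigenvector orthonormality
  V <- p$vectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  # centring: the mean structure projects to zero
  expect_equal(mean(p$projections$pc1), 0, tolerance = 1e-8)
  # sign convention: the most extended frame projects negative on PC1
  rg <- apply(matrix(x[, sel, ], nrow = 200), 1, function(v) {
    m <- matrix(v, ncol = 3)
    sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  })
  expect_lt(p$projections$pc1[which.max(rg)], 0)
  expect_error(pcaTails(list(a = staticTraj(matrix(0, 5, 3), nFrames = 1))),
               "2 frames")
})

test_that("hexasome toy particles show larger RMSF on the unwrapped-side tail", {
  sp <- toyParticleSpec("hexasome", nFrames = 600, seed = 23)
  tr <- simulateParticleTrajectory(sp)
  al <- superposeTrajectory(tr, selectAtoms(tr, role = "core"))$trajectory
  prof <- rmsfProfile(list(al))
  a <- prof$rmsf[prof$chain == "A"]  # unwrapped side
  e <- prof$rmsf[prof$chain == "E"]  # dimer side
  expect_gte(mean(a > e), 0.8)
})

test_that("multi-model PDB files round trip through an independent reader", {
  sp <- toyParticleSpec("tetrasome", nFrames = 3, seed = 2)
  tr <- simulateParticleTrajectory(sp)
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeTrajectoryPdb(tr, f)
  back <- readTrajectoryPdb(f, topology = topology(tr))
  expect_equal(nFrames(back), 3)
  expect_equal(coords(back), coords(tr), tolerance = 2e-3)
  # topology TSV round trip
  ft <- tempfile(fileext = ".tsv")
  on.exit(unlink(ft), add = TRUE)
  writeTopologyTsv(topology(tr), ft)
  expect_equal(readTopologyTsv(ft), topology(tr))
})
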