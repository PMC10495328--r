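# Shared fixtures and independent oracles used across the suite.

cross_v <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Brute-force projection oracle for the signed angulation/inclination of one
# landmark triplet, written directly from the geometric definitions (explicit
# plane bases and 2-D projections), independent of the package's atan2 path.
oracle_angles <- function(M, D, A, superior, lingual) {
  mid <- (M + D) / 2
  axis <- (A - mid) / sqrt(sum((A - mid)^2))
  dm <- (D - M) / sqrt(sum((D - M)^2))
  # angulation plane: contains M-D direction and superior; basis (distal', s)
  n_ang <- cross_v(dm, superior)
  n_ang <- n_ang / sqrt(sum(n_ang^2))
  distal_ip <- dm - sum(dm * superior) * superior
  distal_ip <- distal_ip / sqrt(sum(distal_ip^2))
  u <- sum(axis * distal_ip)
  v <- sum(axis * superior)
  ang <- atan2(u, abs(v)) * 180 / pi
  # inclination plane: spanned by superior and the in-plane normal direction
  w <- sum(axis * n_ang)
  sgn <- sign(sum(n_ang * lingual))
  inc <- atan2(w * sgn, abs(v)) * 180 / pi
  c(angulation = ang, inclination = inc)
}

# single-tooth fixture: template tooth at the origin (axis +z), crest disc at
# the cervical plane, per-side bone blocks with designed defects
single_tooth_fixture <- function(defects = NULL, fdi = 11, n_seg = 24) {
  tpl <- tooth_template(fdi)
  bt <- build_tooth(tpl, diag(3), c(0, 0, 0), mesh = TRUE, n_seg = n_seg)
  bone <- orthosetup:::merge_meshes(orthosetup:::bone_blocks_for_tooth(
    c(0, 0), c(1, 0), c(0, 1), crest_z = 0, sigma = 1, defects = defects
  ))
  disc <- crest_disc(c(0, 0, 0), c(0, 0, 1), fdi = fdi)
  list(
    tooth = bt$mesh, bone = bone, disc = disc,
    landmarks = bt$landmarks, midpoint = c(0, 0, 0), lingual = c(0, 1, 0)
  )
}

make_frame_z <- function() {
  occlusal_frame(c(30, 0, 0), c(-30, 0, 0), c(0, 40, 0), c(0, 20, 10))
}
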