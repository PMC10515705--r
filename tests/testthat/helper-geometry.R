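# Shared fixtures and independent numeric oracles for the test suite.

# Random valid single-view landmark set in a canonical frame: neck axis
# horizontal through the head centre, screw axis guaranteed to intersect
# the head circle.  Returns the view_landmarks plus the raw draw so tests
# can transform it (mirror, magnify) exactly.
random_view_draw <- function(view = "AP", with_calcar = (view == "AP")) {
  cx <- runif(1, -50, 50); cy <- runif(1, -50, 50)
  r <- runif(1, 18, 28)
  ang <- runif(1, -20, 20) * pi / 180       # screw rotation from neck axis
  h <- runif(1, -0.7, 0.7) * r              # perpendicular offset at centre
  d <- runif(1, 2, 18)                      # tip depth to the far surface
  dir <- c(cos(ang), sin(ang))
  nperp <- c(-dir[2], dir[1])
  B <- c(cx, cy) + h * nperp + sqrt(r^2 - h^2) * dir
  tip <- B - d * dir
  diam <- runif(1, 10, 16)
  list(cx = cx, cy = cy, r = r, ang = ang, h = h, d = d,
       dir = dir, tip = tip, B = B, diam = diam,
       calcar = if (with_calcar) c(cx - 3, cy - runif(1, 0.6, 0.85) * r)
                else NULL,
       view = view)
}

draw_to_view <- function(g, scale = 1) {
  view_landmarks(g$view,
                 head_center = scale * c(g$cx, g$cy), head_radius = scale * g$r,
                 neck_axis_point = scale * c(g$cx - 30, g$cy),
                 neck_axis_dir = c(1, 0),
                 screw_tip = scale * g$tip, screw_axis_dir = g$dir,
                 screw_diameter_measured = scale * g$diam,
                 calcar_point = if (is.null(g$calcar)) NULL else scale * g$calcar)
}

# reflect a canonical-frame draw across the (horizontal) neck axis
mirror_draw <- function(g) {
  g$tip[2] <- 2 * g$cy - g$tip[2]
  g$B[2] <- 2 * g$cy - g$B[2]
  g$dir[2] <- -g$dir[2]
  g$ang <- -g$ang
  g$h <- -g$h
  if (!is.null(g$calcar)) g$calcar[2] <- 2 * g$cy - g$calcar[2]
  g
}

random_case <- function(ap_scale = 1, lat_scale = 1) {
  case_radiographs("rc", draw_to_view(random_view_draw("AP"), ap_scale),
                   draw_to_view(random_view_draw("LAT"), lat_scale))
}

# Independent oracle for the circle-line far intersection: bracket the
# roots of |o + t d - c|^2 - r^2 by a dense scan in t and polish each with
# uniroot; return the far point (largest root).  Never uses the package's
# closed form.
sweep_far_intersection <- function(origin, dir, center, radius) {
  g <- function(t) sum((origin + t * dir - center)^2) - radius^2
  span <- 4 * (radius + sqrt(sum((origin - center)^2)))
  ts <- seq(-span, span, length.out = 4001)
  gs <- vapply(ts, g, numeric(1))
  roots <- c()
  for (i in seq_len(length(ts) - 1)) {
    if (gs[i] == 0) roots <- c(roots, ts[i])
    else if (gs[i] * gs[i + 1] < 0)
      roots <- c(roots, uniroot(g, c(ts[i], ts[i + 1]), tol = 1e-12)$root)
  }
  if (!length(roots)) return(NULL)
  tfar <- max(roots)
  list(point = origin + tfar * dir, t = tfar)
}

# Brute-force AUC by explicit pair counting
brute_auc <- function(pos, neg) {
  s <- 0
  for (x in pos) s <- s + sum(x > neg) + 0.5 * sum(x == neg)
  s / (length(pos) * length(neg))
}
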