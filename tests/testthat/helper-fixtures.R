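# shared fixtures, built in code and memoized across test files

rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# a tiny 4-channel section with hand-placed intensities
tiny_section <- function(h = 40, w = 50, pixel_size = 1) {
  ch <- function(fill = 0) matrix(fill, h, w)
  ins <- ch(); ins[10:20, 10:20] <- 200
  glu <- ch(); glu[25:30, 30:36] <- 180
  som <- ch()
  nuc <- ch(); nuc[14:16, 14:16] <- 220
  section_image(list(insulin = ins, glucagon = glu, somatostatin = som,
                     nuclei = nuc), pixel_size = pixel_size)
}

# manual thresholds at half the rendered signal level
manual_cfg <- function(params, ...) {
  thr <- as.list(stats::setNames(
    rep(params$signal_level / 2, length(params$hormones) + 1L),
    c(params$hormones, "nuclei")))
  run_config(pixel_size = params$pixel_size, thresholds = thr, ...)
}

# memoized synthetic sections (generation is the expensive step)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# mid-sized section used by several suites
std_section <- function() fixture("std_section", function() {
  p <- synth_params(frame_um = c(900, 900), n_islets = 14, seed = 11,
                    exocrine_nuclei_per_mm2 = 300,
                    n_exclusions = 1, exclusion_radius_um = c(70, 90))
  c(generate_section(p), list(params = p))
})

# 2000 x 2000 px section at 10% noise, the parameter-recovery condition
big_section <- function() fixture("big_section", function() {
  p <- synth_params(seed = 7, noise_sd = 20)
  c(generate_section(p), list(params = p))
})

big_result <- function() fixture("big_result", function() {
  g <- big_section()
  quantify_section(g$section, g$contours,
                   manual_cfg(g$params, min_area_um2 = 20))
})

# match each truth islet to the nearest pipeline islet centroid
match_islets <- function(truth_islets, islets) {
  vapply(seq_len(nrow(truth_islets)), function(i) {
    d <- sqrt((islets$centroid_x_um - truth_islets$x_um[i])^2 +
                (islets$centroid_y_um - truth_islets$y_um[i])^2)
    which.min(d)
  }, integer(1))
}
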