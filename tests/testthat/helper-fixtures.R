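# shared fixtures: everything is built in code at test time

tiny_atlas <- function() make_atlas(32, 32, 0.31)

# wrap a pixels-x-time HbT matrix (or h x w x t array) as a hemo_movie with
# zero HbR, so hbt == hbo == the given data
toy_movie <- function(x, h = NULL, w = NULL, frame_rate = 1, mask = NULL) {
  if (is.matrix(x)) {
    stopifnot(!is.null(h), !is.null(w))
    x <- array(x, c(h, w, ncol(x)))
  }
  d <- dim(x)
  hemo_movie(hbo = x, hbr = array(0, d), frame_rate = frame_rate,
             mask = mask %||% matrix(TRUE, d[1], d[2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-node network on a tiny atlas with a single tunable edge
two_node_network <- function(atlas, r, noise_sd = 0, duration = 300,
                             sampling_rate = 1, ...) {
  nodes <- data.frame(name = c("a_L", "a_R"),
                      row = round(0.45 * atlas$height) * c(1, 1),
                      col = round(c(0.28, 0.72) * atlas$width),
                      sigma = 2, hemisphere = c("L", "R"))
  edges <- if (abs(r) > 0) data.frame(from = "a_L", to = "a_R", r = r)
           else NULL
  network_spec(nodes, edges, noise_sd = noise_sd, duration = duration,
               sampling_rate = sampling_rate, ...)
}
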