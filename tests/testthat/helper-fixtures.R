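# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

with_fix <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

tiny_phantom <- function() {
  with_fix("tiny", phantom_head(c(24, 24, 24), voxel_size = 4,
                                fold_amplitude = 0.1, seed = 1))
}

tiny_fields <- function() {
  with_fix("tiny_pf", property_fields(tiny_phantom()))
}

# Scaled-down forward study: 32^3 phantom at 3 mm, one deep 10 Hz
# white-matter source, 48 electrodes, 1 s at 64 Hz.
study32 <- function() {
  with_fix("study32", {
    g <- phantom_head(c(32, 32, 32), voxel_size = 3,
                      fold_amplitude = 0.1, seed = 1)
    pf <- property_fields(g)
    sen <- place_electrodes(g, 48, seed = 2)
    w <- voxel_to_world(g, c(21, 17, 17))
    src <- data.frame(x = w[1], y = w[2], z = w[3], freq = 10,
                      amplitude = 1)
    st <- synthesize_study(g, pf, src, duration = 1, fs = 64,
                           sensors = sen)
    list(g = g, pf = pf, sen = sen, src = src, st = st,
         brain = g$labels >= 4)
  })
}

fit32 <- function() {
  with_fix("fit32", spectre(study32()$st$recording, study32()$pf,
                            band = c(8, 12)))
}

# Wrap a bare space x time array as a wave_field.
mk_wave <- function(ph, dt = 0.1, spacing = 1, grid = NULL) {
  nd <- length(dim(ph))
  structure(list(phi = ph, dt = dt,
                 times = (seq_len(dim(ph)[nd]) - 1) * dt,
                 spacing = spacing, grid = grid),
            class = "wave_field")
}
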