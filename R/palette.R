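# Colour conventions shared by the renderer and the vision module.

# Fixed reference anchors used to assign broad labels to colour centroids.
# Pure-hue anchors in RGB space; nearest anchor (Euclidean) wins.
reference_palette <- function() {
  list(
    yellow = c(255, 255, 0),
    green  = c(0, 255, 0),
    orange = c(255, 165, 0),
    red    = c(255, 0, 0),
    blue   = c(0, 0, 255),
    black  = c(0, 0, 0),
    white  = c(255, 255, 255),
    gray   = c(128, 128, 128)
  )
}

# Palette the fixture renderer draws with. Saturated enough that every colour
# is nearest its intended anchor (so rendered pixels classify to the broad
# label the algorithm expects).
render_palette <- function() {
  list(
    background  = c(255, 255, 255),
    band_red    = c(220, 60, 60),    # Phred [0, 20): poor quality
    band_orange = c(250, 180, 80),   # Phred [20, 28): reasonable quality
    band_green  = c(60, 220, 60),    # Phred [28, max]: good quality
    box_yellow  = c(240, 240, 80),   # interquartile-range box
    median_red  = c(255, 0, 0),      # median segment
    mean_blue   = c(0, 0, 255),      # mean poly-line
    ink         = c(0, 0, 0)         # axes, ticks, labels, whiskers
  )
}
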