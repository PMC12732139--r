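# Shared fixtures, cached so expensive renders happen once per test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# canonical noiseless fixture: plateau 38, decay from 175, rate 0.5/base
std_profile <- function() {
  cached("std_profile", simulate_profile(profile_spec(read_length = 250, noise_sd = 0)))
}

std_render <- function() cached("std_render", render_plot(std_profile()))

std_color_map <- function() {
  cached("std_color_map", build_color_map(std_render()$image, vision_params()))
}

flat_profile <- function(plateau) {
  simulate_profile(profile_spec(read_length = 250, plateau_q = plateau,
                                decay_start = 300, noise_sd = 0))
}

# uniform-quality profile with one bin per position; oracle unit tests use it
# because truncation then falls exactly on a position boundary
per_position_profile <- function(q25_by_pos) {
  n <- length(q25_by_pos)
  quality_profile(data.frame(start = 1:n, end = 1:n,
                             mean = q25_by_pos, median = q25_by_pos,
                             q25 = q25_by_pos, q75 = q25_by_pos,
                             q10 = q25_by_pos, q90 = q25_by_pos))
}

# Independent reference for the table route: explicit right-to-left loop,
# no shared code with oracle_trim.
exhaustive_trim_ref <- function(profile, threshold) {
  b <- profile$bins
  for (i in rev(seq_len(nrow(b)))) {
    if (b$q25[i] >= threshold) {
      if (i == nrow(b)) {
        return(list(position = profile$read_length, status = "never_below"))
      }
      return(list(position = b$end[i], status = "found"))
    }
  }
  list(position = 0L, status = "always_below")
}

# Verification grid: read lengths {150, 250, 300}, decay onsets spanning
# 40-95% of the read, decay rates 0.2-1.0 Phred/base, noise sd {0, 1, 2}.
grid_specs <- function(n = 50, base_seed = 1L) {
  rl_set <- c(150L, 250L, 300L)
  rate_set <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  noise_set <- c(0, 1, 2)
  fracs <- seq(0.40, 0.95, length.out = n)
  lapply(seq_len(n), function(i) {
    rl <- rl_set[(i - 1) %% 3 + 1]
    profile_spec(read_length = rl,
                 decay_start = max(1, round(fracs[i] * rl)),
                 decay_rate = rate_set[(i - 1) %% 5 + 1],
                 noise_sd = noise_set[((i - 1) %/% 3) %% 3 + 1],
                 seed = base_seed * 1000L + i)
  })
}

# Full pipeline over the grid; images are not retained (memory).
acceptance_grid <- function() {
  cached("acceptance_grid", {
    lapply(grid_specs(50), function(spec) {
      prof <- simulate_profile(spec)
      r <- render_plot(prof)
      sc <- r$sidecar
      html <- tempfile(fileext = ".html")
      wrap_html(r$image, prof$read_length, "grid_sample", path = html)
      rep <- parse_fastqc_html(html)
      unlink(html)
      pred <- predict_trim(rep, vision_params())
      orac <- oracle_trim(prof, 20)
      params <- vision_params()
      cm <- build_color_map(r$image, params)
      geom <- calibrate_x_axis(r$image, params,
                               locate_threshold_row(r$image, params, cm))
      x_match <- merge(sc$x_tick_cols, geom$x_ticks, by = "position",
                       all.x = TRUE, suffixes = c("_true", "_seen"))
      y_match <- merge(sc$y_tick_rows, geom$y_ticks, by = "score",
                       all.x = TRUE, suffixes = c("_true", "_seen"))
      list(spec = spec,
           bin_width = spec$bin_width,
           gt_trunc = sc$ground_truth_truncation,
           gt_status = sc$ground_truth_status,
           pred_trunc = pred$truncation_position,
           pred_status = pred$status,
           oracle_trunc = orac$truncation_position,
           oracle_status = orac$status,
           ref = exhaustive_trim_ref(prof, 20),
           x_ticks_exact = !anyNA(x_match$col_seen) &&
             all(abs(x_match$col_true - x_match$col_seen) <= 2),
           y_ticks_exact = !anyNA(y_match$row_seen) &&
             all(abs(y_match$row_true - y_match$row_seen) <= 1),
           n_x_ticks = nrow(sc$x_tick_cols),
           n_y_ticks = nrow(sc$y_tick_rows))
    })
  })
}
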