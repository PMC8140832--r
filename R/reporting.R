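#' Phenotype color map
#'
#' Fixed dashboard semantics: early decliners red, middle yellow, late
#' green.
#' @export
animation_colors <- c(early = "red", middle = "yellow", late = "green")

PHENOTYPE_ANIM_ORDER <- c("late", "middle", "early")
ANIM_PHASES <- c("highlight", "smooth", "collapse")

#' Build the frame script of a center animation
#'
#' Deterministic frame list for the multistage center animation:
#' phenotypes in the order late, then middle, then early; within each
#' phenotype the phases highlight (observed trajectories colored),
#' smooth (observed trajectories morph into fitted curves), and collapse
#' (fitted curves merge into the cell mean). Phenotypes absent from the
#' center are skipped. The rate-of-change variant uses the same script
#' (curves shown, shaded by class, averaged).
#'
#' @param labels data.frame with `patient_id` and `label` for the
#'   center's patients.
#' @param center_id center identifier carried into the script.
#' @param frames_per_phase frames rendered per phase transition.
#' @return data.frame of class `animation_script` with columns `frame`,
#'   `phenotype`, `phase`, `progress`; attributes `center_id` and
#'   `colors`.
#' @export
build_animation_script <- function(labels, center_id = "center",
                                   frames_per_phase = 10) {
  stopifnot(frames_per_phase >= 1)
  labs <- as.character(labels$label)
  if (length(labs) == 0) stop("center has no patients")
  present <- PHENOTYPE_ANIM_ORDER[PHENOTYPE_ANIM_ORDER %in% labs]
  rows <- list()
  for (ph in present) {
    for (phase in ANIM_PHASES) {
      rows[[length(rows) + 1]] <- data.frame(
        phenotype = ph, phase = phase,
        progress = seq_len(frames_per_phase) / frames_per_phase,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$frame <- seq_len(nrow(out))
  out <- out[, c("frame", "phenotype", "phase", "progress")]
  attr(out, "center_id") <- center_id
  attr(out, "colors") <- animation_colors
  class(out) <- c("animation_script", class(out))
  out
}

#' Randomly select display centers
#'
#' Seeded sample of `per_category` centers from each size category
#' (small, medium, large). Categories with fewer centers contribute all
#' of them, with a warning.
#'
#' @param profiles data.frame with `center_id` and `size_category`.
#' @param per_category centers per category.
#' @param seed RNG seed for the sample.
#' @return character vector of center ids, ordered small, medium, large.
#' @export
select_display_centers <- function(profiles, per_category = 3, seed = 1) {
  set.seed(seed)
  out <- character(0)
  for (cat in c("small", "medium", "large")) {
    ids <- sort(profiles$center_id[profiles$size_category == cat])
    if (length(ids) < per_category) {
      warning("category '", cat, "' has only ", length(ids), " centers; taking all")
      sel <- ids
    } else {
      sel <- sort(sample(ids, per_category))
    }
    out <- c(out, sel)
  }
  out
}

# ---- frame rendering -------------------------------------------------

# Assemble the per-center data needed to draw animation frames.
center_plot_data <- function(cohort, model, labels, center_id) {
  pats <- cohort$primary$patient_id[cohort$primary$center_id == center_id]
  if (length(pats) == 0) stop("center has no patients: ", center_id)
  fc <- fitted_curves(model)
  keep <- intersect(pats, colnames(fc$fit))
  lab <- label_lookup(labels)[keep]
  enc <- cohort$encounters[cohort$encounters$patient_id %in% keep, ]
  list(center_id = center_id, patients = keep, labels = lab,
       encounters = split(enc[, c("encounter_age", "fev1pp")], enc$patient_id),
       fit = fc$fit[, keep, drop = FALSE],
       deriv = fc$deriv[, keep, drop = FALSE],
       grid = model$grid)
}

# Draw one frame of the trajectory or rate animation onto the active device.
draw_frame <- function(cd, script_row, done, kind = c("trajectory", "rate")) {
  kind <- match.arg(kind)
  grid <- cd$grid
  if (kind == "trajectory") {
    ylim <- range(vapply(cd$encounters, function(d) range(d$fev1pp), numeric(2)),
                  cd$fit)
    ylab <- "FEV1 (% predicted)"
  } else {
    ylim <- range(cd$deriv)
    ylab <- "Rate of change (% predicted/year)"
  }
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::plot(NA, xlim = range(grid), ylim = ylim, xlab = "Age (years)",
                 ylab = ylab, main = cd$center_id)
  base_col <- "grey70"
  mean_curve <- function(ph) {
    cols <- which(cd$labels == ph)
    rowMeans((if (kind == "trajectory") cd$fit else cd$deriv)[, cols, drop = FALSE])
  }
  for (i in seq_along(cd$patients)) {
    p <- cd$patients[i]
    ph <- cd$labels[i]
    col <- base_col
    if (ph %in% done) next  # collapsed already; mean drawn below
    active <- !is.null(script_row) && ph == script_row$phenotype
    if (kind == "trajectory") {
      d <- cd$encounters[[p]]
      if (!active) {
        graphics::lines(d$encounter_age, d$fev1pp, col = base_col)
      } else {
        col <- animation_colors[[ph]]
        pr <- script_row$progress
        if (script_row$phase == "highlight") {
          graphics::lines(d$encounter_age, d$fev1pp, col = col)
        } else if (script_row$phase == "smooth") {
          fit_at <- interp_curve(grid, cd$fit[, p], d$encounter_age)
          graphics::lines(d$encounter_age,
                          (1 - pr) * d$fev1pp + pr * fit_at, col = col)
        } else {  # collapse: fitted curves merge into the mean
          m <- mean_curve(ph)
          graphics::lines(grid, (1 - pr) * cd$fit[, p] + pr * m, col = col)
        }
      }
    } else {
      y <- cd$deriv[, p]
      if (!active) {
        graphics::lines(grid, y, col = base_col)
      } else {
        col <- animation_colors[[ph]]
        pr <- script_row$progress
        if (script_row$phase == "highlight") {
          graphics::lines(grid, y, col = col)
        } else if (script_row$phase == "smooth") {
          graphics::lines(grid, y, col = col, lwd = 1 + pr)
        } else {
          m <- mean_curve(ph)
          graphics::lines(grid, (1 - pr) * y + pr * m, col = col, lwd = 2)
        }
      }
    }
  }
  for (ph in done) {
    graphics::lines(grid, mean_curve(ph), col = animation_colors[[ph]], lwd = 3)
  }
}

# Render every frame of a script to PNG and read back as arrays.
render_animation_frames <- function(cd, script, kind, width = 320, height = 240) {
  frames <- vector("list", nrow(script) + 1)
  tmp <- tempfile(fileext = ".png")
  on.exit(unlink(tmp))
  order_seen <- unique(script$phenotype)
  for (i in seq_len(nrow(script))) {
    row <- script[i, ]
    done <- order_seen[seq_len(match(row$phenotype, order_seen) - 1)]
    grDevices::png(tmp, width = width, height = height)
    draw_frame(cd, row, done, kind)
    grDevices::dev.off()
    frames[[i]] <- png::readPNG(tmp)
  }
  ## final hold frame: everything collapsed
  grDevices::png(tmp, width = width, height = height)
  draw_frame(cd, NULL, order_seen, kind)
  grDevices::dev.off()
  frames[[nrow(script) + 1]] <- png::readPNG(tmp)
  frames
}

# Static thumbnail: per-phenotype mean curves for one center.
render_center_thumbnail <- function(cd, path, kind, width = 320, height = 240) {
  grDevices::png(path, width = width, height = height)
  draw_frame(cd, NULL, unique(PHENOTYPE_ANIM_ORDER[PHENOTYPE_ANIM_ORDER %in% cd$labels]),
             kind)
  grDevices::dev.off()
  invisible(path)
}

# ---- html ------------------------------------------------------------

html_page <- function(title, body) {
  paste0("<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\">\n<title>",
         title, "</title>\n<style>body{font-family:sans-serif;margin:2em;}",
         ".tile{display:inline-block;margin:8px;text-align:center;}",
         ".row{margin-bottom:1em;}</style>\n</head>\n<body>\n<h1>", title,
         "</h1>\n", body, "\n</body>\n</html>\n")
}

DASHBOARD_LINKS <- data.frame(
  file = c("fpca_animations.html", "rate_animations.html",
           "mean_trajectories.html", "mean_rates.html", "additional.html"),
  title = c("Center-Level FPCA Animations",
            "Center-Level Rate-of-Change Animations",
            "Center-Level Mean Predicted Trajectories",
            "Center-Level Mean Predicted Rate of Change",
            "Additional Displays"),
  stringsAsFactors = FALSE)

#' Render the benchmarking dashboard
#'
#' Writes a self-contained static dashboard: a landing page with five
#' links (FPCA animations, rate-of-change animations, mean predicted
#' trajectories, mean predicted rates, and an additional-displays
#' placeholder), one animated GIF page per selected center for both the
#' trajectory and the rate sequence, and summary thumbnail pages whose
#' rows are ordered small, medium, large. Only opaque patient/center ids
#' appear in the output. Rendering is deterministic given its inputs and
#' the seed.
#'
#' @param cohort a `cohort_table`.
#' @param model an `fpca_model` fitted to the cohort.
#' @param labels a `phenotype_assignment`.
#' @param out_dir output directory (created; must be writable).
#' @param seed seed for display-center selection.
#' @param per_category selected centers per size category.
#' @param frames_per_phase animation frames per phase transition.
#' @param width,height image size in pixels.
#' @param delay_cs GIF inter-frame delay (hundredths of a second).
#' @return `out_dir`, invisibly.
#' @export
render_dashboard <- function(cohort, model, labels, out_dir,
                             seed = 1, per_category = 3,
                             frames_per_phase = 4,
                             width = 320, height = 240, delay_cs = 25) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  profiles <- center_profiles(patient_table(cohort, model, labels))
  selected <- select_display_centers(profiles, per_category, seed)
  sel_prof <- profiles[match(selected, profiles$center_id), ]

  ## landing page
  links <- paste0("<ul>\n", paste0(
    "<li><a href=\"", DASHBOARD_LINKS$file, "\">", DASHBOARD_LINKS$title,
    "</a></li>", collapse = "\n"), "\n</ul>")
  writeLines(html_page("Rapid Lung Function Decline: Center Dashboard", links),
             file.path(out_dir, "index.html"))

  tile <- function(href, img, caption) {
    paste0("<div class=\"tile\"><a href=\"", href, "\"><img src=\"", img,
           "\" width=\"", width, "\" height=\"", height, "\"></a><br>",
           caption, "</div>")
  }

  anim_body <- function(kind) {
    rows <- character(0)
    for (cat in c("small", "medium", "large")) {
      ids <- sel_prof$center_id[sel_prof$size_category == cat]
      if (length(ids) == 0) next
      tiles <- vapply(ids, function(cid) {
        tile(sprintf("center_%s_%s.html", cid, kind),
             sprintf("thumb_%s_%s.png", cid, kind),
             sprintf("%s (%s)", cid, cat))
      }, character(1))
      rows <- c(rows, paste0("<div class=\"row\">", paste(tiles, collapse = ""),
                             "</div>"))
    }
    paste(rows, collapse = "\n")
  }

  summary_body <- function(kind) {
    rows <- character(0)
    for (cat in c("small", "medium", "large")) {
      ids <- sel_prof$center_id[sel_prof$size_category == cat]
      if (length(ids) == 0) next
      imgs <- vapply(ids, function(cid) {
        paste0("<span class=\"tile\"><img src=\"", sprintf("thumb_%s_%s.png", cid, kind),
               "\" width=\"", width, "\" height=\"", height, "\"><br>", cid,
               " (", cat, ")</span>")
      }, character(1))
      rows <- c(rows, paste0("<div class=\"row\">", paste(imgs, collapse = ""),
                             "</div>"))
    }
    paste(rows, collapse = "\n")
  }

  for (cid in selected) {
    cd <- center_plot_data(cohort, model, labels, cid)
    script <- build_animation_script(
      data.frame(patient_id = cd$patients, label = unname(cd$labels)),
      center_id = cid, frames_per_phase = frames_per_phase)
    for (kind in c("trajectory", "rate")) {
      frames <- render_animation_frames(cd, script, kind, width, height)
      gif <- sprintf("anim_%s_%s.gif", cid, kind)
      write_gif(frames, file.path(out_dir, gif), delay_cs = delay_cs)
      render_center_thumbnail(cd, file.path(out_dir,
                                            sprintf("thumb_%s_%s.png", cid, kind)),
                              kind, width, height)
      body <- paste0("<p><a href=\"", DASHBOARD_LINKS$file[match(kind, c("trajectory", "rate"))],
                     "\">Back</a></p>\n<img src=\"", gif, "\" width=\"", width,
                     "\" height=\"", height, "\">")
      writeLines(html_page(paste0("Center ", cid, " — ",
                                  ifelse(kind == "trajectory",
                                         "FPCA animation", "rate-of-change animation")),
                           body),
                 file.path(out_dir, sprintf("center_%s_%s.html", cid, kind)))
    }
  }

  writeLines(html_page(DASHBOARD_LINKS$title[1],
                       paste0("<p><a href=\"index.html\">Back</a></p>\n",
                              anim_body("trajectory"))),
             file.path(out_dir, "fpca_animations.html"))
  writeLines(html_page(DASHBOARD_LINKS$title[2],
                       paste0("<p><a href=\"index.html\">Back</a></p>\n",
                              anim_body("rate"))),
             file.path(out_dir, "rate_animations.html"))
  writeLines(html_page(DASHBOARD_LINKS$title[3],
                       paste0("<p><a href=\"index.html\">Back</a></p>\n",
                              summary_body("trajectory"))),
             file.path(out_dir, "mean_trajectories.html"))
  writeLines(html_page(DASHBOARD_LINKS$title[4],
                       paste0("<p><a href=\"index.html\">Back</a></p>\n",
                              summary_body("rate"))),
             file.path(out_dir, "mean_rates.html"))
  writeLines(html_page(DASHBOARD_LINKS$title[5],
                       "<p><a href=\"index.html\">Back</a></p>\n<p>Reserved for future displays.</p>"),
             file.path(out_dir, "additional.html"))
  invisible(out_dir)
}

#' Check that all internal dashboard links resolve
#'
#' Crawls every HTML file in a rendered dashboard directory and verifies
#' that each local `href`/`src` target exists.
#'
#' @param dir dashboard directory.
#' @return character vector of missing targets (empty when all resolve).
#' @export
check_dashboard_links <- function(dir) {
  pages <- list.files(dir, pattern = "\\.html$", full.names = TRUE)
  missing <- character(0)
  for (p in pages) {
    txt <- paste(readLines(p, warn = FALSE), collapse = "\n")
    refs <- regmatches(txt, gregexpr("(href|src)=\"[^\"]+\"", txt))[[1]]
    refs <- sub("^(href|src)=\"", "", refs)
    refs <- sub("\"$", "", refs)
    refs <- refs[!grepl("^(https?:|mailto:|#)", refs)]
    for (r in refs) {
      if (!file.exists(file.path(dir, r))) missing <- c(missing, r)
    }
  }
  unique(missing)
}
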