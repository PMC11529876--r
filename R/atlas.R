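## Static HTML atlas pages.
##
## The viewer itself is an external, vendored script (a deep-zoom
## viewer plus its scalebar plug-in) living under `openseadragon/` in
## the site tree; this module only *configures* it: it assembles
## deterministic, well-formed HTML with one container per viewer, a
## floating scalebar calibrated through an integer PixelsPerMeter
## value, optional switchable overlay pyramids, and responsive CSS so
## pages scale to different screens and work from `file://`.  Page
## generation is pure text assembly and never touches pixel data.

#' Integer PixelsPerMeter calibration from the pixel size
#'
#' The floating scalebar is driven by an integer pixels-per-meter
#' value: `round(1e9 / pixel_size_nm)`.
#'
#' @param pixel_size_nm physical pixel size in nm per pixel (> 0).
#' @return integer-valued number of pixels per metre.
#' @export
pixels_per_meter <- function(pixel_size_nm) {
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    config_error("pixel_size_nm must be > 0")
  round(1e9 / pixel_size_nm)
}

#' Physical display length of a feature at print magnification
#'
#' At magnification M, a feature of physical length L occupies L x M on
#' the display medium: at 30,000x, 1 micrometre of specimen spans 3 cm.
#'
#' @param feature_length_um feature length in micrometres (>= 0).
#' @param magnification display magnification factor (> 0).
#' @return display length in centimetres, with a `display` attribute
#'   holding a human-readable value (cm when >= 1 cm, mm or um below).
#' @export
projected_length <- function(feature_length_um, magnification) {
  if (feature_length_um < 0 || magnification <= 0)
    config_error("feature length must be >= 0 and magnification > 0")
  cm <- feature_length_um * magnification * 1e-4
  label <- if (cm == 0) "0"
  else if (cm >= 1) sprintf("%g cm", cm)
  else if (cm >= 0.1) sprintf("%g mm", cm * 10)
  else sprintf("%g um", cm * 1e4)
  structure(cm, display = label)
}

#' Overlay specification for a switchable atlas overlay
#'
#' @param label button label.
#' @param dzi_path overlay pyramid descriptor path, relative to the page.
#' @param color overlay colour (`#rrggbb`).
#' @param alpha overlay opacity in `[0, 1]` when visible.
#' @param default_visible initial visibility.
#' @return an `overlay_spec` object.
#' @export
overlay_spec <- function(label, dzi_path, color = "#ff2222", alpha = 0.35,
                         default_visible = FALSE) {
  if (!grepl("^#[0-9a-fA-F]{6}$", color))
    config_error("overlay color must be #rrggbb")
  if (alpha < 0 || alpha > 1) config_error("overlay alpha must be in [0, 1]")
  structure(list(label = label, dzi_path = dzi_path, color = color,
                 alpha = alpha, default_visible = isTRUE(default_visible)),
            class = "overlay_spec")
}

#' Configuration of one viewer container
#'
#' @param container_id unique HTML id of the container div.
#' @param dzi_path base pyramid descriptor path, relative to the page.
#' @param pixel_size_nm physical pixel size; converted to the integer
#'   PixelsPerMeter the scalebar needs.
#' @param scalebar list of scalebar options: `location` (e.g.
#'   `"BOTTOM_LEFT"`), `color`, `bar_thickness` (px).
#' @param overlays list of [overlay_spec()].
#' @param size_css CSS width of the container (percentage or px).
#' @return a `viewer_config` object.
#' @export
viewer_config <- function(container_id, dzi_path, pixel_size_nm,
                          scalebar = list(), overlays = list(),
                          size_css = "90%") {
  if (!grepl("^[A-Za-z][A-Za-z0-9_-]*$", container_id))
    config_error("container_id must be a valid HTML id: %s", container_id)
  sb <- utils::modifyList(list(location = "BOTTOM_LEFT", color = "black",
                               bar_thickness = 4), scalebar)
  extra <- setdiff(names(scalebar), c("location", "color", "bar_thickness"))
  if (length(extra))
    config_error("unknown scalebar option: %s", extra[1])
  structure(list(container_id = container_id, dzi_path = dzi_path,
                 pixels_per_meter = pixels_per_meter(pixel_size_nm),
                 pixel_size_nm = pixel_size_nm, scalebar = sb,
                 overlays = overlays, size_css = size_css),
            class = "viewer_config")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Inline script for one container.  Kept XML-safe (no <, >, &) so the
# page parses with a strict parser.
container_script <- function(cfg) {
  ovl_js <- ""
  if (length(cfg$overlays)) {
    items <- vapply(seq_along(cfg$overlays), function(k) {
      o <- cfg$overlays[[k]]
      sprintf(paste0("viewer_%s.addTiledImage({tileSource: \"%s\", ",
                     "opacity: %s, index: %d});"),
              cfg$container_id, o$dzi_path,
              if (o$default_visible) format(o$alpha) else "0", k)
    }, "")
    ovl_js <- paste(items, collapse = "\n")
  }
  paste0(
    sprintf("var viewer_%s = OpenSeadragon({\n", cfg$container_id),
    sprintf("  id: \"%s\",\n", cfg$container_id),
    "  prefixUrl: \"openseadragon/images/\",\n",
    sprintf("  tileSources: \"%s\",\n", cfg$dzi_path),
    "  showNavigator: true\n",
    "});\n",
    sprintf("viewer_%s.scalebar({\n", cfg$container_id),
    sprintf("  pixelsPerMeter: %d,\n", cfg$pixels_per_meter),
    sprintf("  location: \"%s\",\n", cfg$scalebar$location),
    sprintf("  color: \"%s\",\n", cfg$scalebar$color),
    sprintf("  barThickness: %d\n", cfg$scalebar$bar_thickness),
    "});\n",
    if (nzchar(ovl_js)) paste0(ovl_js, "\n") else "")
}

site_css <- paste0(
  "body { font-family: sans-serif; margin: 1em; }\n",
  ".emma-viewer { width: 100%; height: 70vh; background: #111; }\n",
  ".viewer-wrap { margin: 0 auto 1.5em auto; }\n",
  ".emma-overlays button { margin: 0.3em 0.3em 0 0; }\n",
  "@media (max-width: 800px) { .viewer-wrap { width: 100% ! important; } }\n")

toggle_js <- paste0(
  "function emmaToggleOverlay(viewer, index, alpha, btn) {\n",
  "  var item = viewer.world.getItemAt(index);\n",
  "  if (item === undefined) { return; }\n",
  "  var on = item.getOpacity() === 0;\n",
  "  item.setOpacity(on ? alpha : 0);\n",
  "  btn.setAttribute(\"data-on\", on ? \"1\" : \"0\");\n",
  "}\n")

#' Render a static atlas page
#'
#' One container div plus one inline init script per
#' [viewer_config()], in input order, with scalebar configuration and
#' one overlay toggle button per overlay.  Output is deterministic
#' byte-for-byte for fixed inputs and parses as well-formed XML.
#'
#' @param configs list of [viewer_config()]; container ids must be
#'   unique.
#' @param title page title.
#' @param base_dir when given, referenced pyramid paths are resolved
#'   against it and checked for existence.
#' @param verify if `TRUE` (default when `base_dir` is given) a missing
#'   pyramid is a configuration error; if `FALSE` it only warns.
#' @return HTML text.
#' @export
render_page <- function(configs, title = "EM atlas", base_dir = NULL,
                        verify = !is.null(base_dir)) {
  stopifnot(all(vapply(configs, inherits, TRUE, "viewer_config")))
  ids <- vapply(configs, `[[`, "", "container_id")
  if (anyDuplicated(ids))
    config_error("duplicate container_id: %s", ids[duplicated(ids)][1])
  if (!is.null(base_dir)) {
    for (cfg in configs) {
      paths <- c(cfg$dzi_path,
                 vapply(cfg$overlays, `[[`, "", "dzi_path"))
      for (pth in paths) {
        if (!file.exists(file.path(base_dir, pth))) {
          if (verify) config_error("referenced pyramid missing: %s", pth)
          warning(sprintf("referenced pyramid missing: %s", pth))
        }
      }
    }
  }
  blocks <- vapply(configs, function(cfg) {
    buttons <- ""
    if (length(cfg$overlays)) {
      bs <- vapply(seq_along(cfg$overlays), function(k) {
        o <- cfg$overlays[[k]]
        sprintf(paste0("<button data-on=\"%d\" onclick=\"emmaToggleOverlay(",
                       "viewer_%s, %d, %s, this)\">%s</button>"),
                as.integer(o$default_visible), cfg$container_id, k,
                format(o$alpha), html_escape(o$label))
      }, "")
      buttons <- sprintf("<div class=\"emma-overlays\">%s</div>\n",
                         paste(bs, collapse = ""))
    }
    paste0(sprintf("<div class=\"viewer-wrap\" style=\"width:%s\">\n",
                   cfg$size_css),
           sprintf("<div id=\"%s\" class=\"emma-viewer\"></div>\n",
                   cfg$container_id),
           buttons,
           "</div>\n",
           "<script>\n", container_script(cfg), "</script>\n")
  }, "")
  paste0("<!DOCTYPE html>\n",
         "<html lang=\"en\">\n<head>\n",
         "<meta charset=\"utf-8\"></meta>\n",
         sprintf("<title>%s</title>\n", html_escape(title)),
         "<style>\n", site_css, "</style>\n",
         "<script src=\"openseadragon/openseadragon.min.js\"></script>\n",
         "<script src=\"openseadragon/openseadragon-scalebar.js\"></script>\n",
         "</head>\n<body>\n",
         sprintf("<h1>%s</h1>\n", html_escape(title)),
         "<script>\n", toggle_js, "</script>\n",
         paste(blocks, collapse = ""),
         "</body>\n</html>\n")
}

#' Render a project overview page linking several atlases
#'
#' @param entries list of lists with `thumbnail`, `link`, `caption`.
#' @param title page title.
#' @return HTML text (deterministic bytes).
#' @export
render_project_index <- function(entries = list(), title = "EM atlas project") {
  cells <- vapply(entries, function(e) {
    paste0("<div class=\"cell\">",
           sprintf("<a href=\"%s\">", e$link),
           if (!is.null(e$thumbnail))
             sprintf("<img src=\"%s\" alt=\"%s\"></img>", e$thumbnail,
                     html_escape(e$caption %||% "")) else "",
           sprintf("<p>%s</p>", html_escape(e$caption %||% "")),
           "</a></div>\n")
  }, "")
  paste0("<!DOCTYPE html>\n<html lang=\"en\">\n<head>\n",
         "<meta charset=\"utf-8\"></meta>\n",
         sprintf("<title>%s</title>\n", html_escape(title)),
         "<style>\n.grid { display: flex; flex-wrap: wrap; gap: 1em; }\n",
         ".cell img { max-width: 240px; }\n</style>\n",
         "</head>\n<body>\n",
         sprintf("<h1>%s</h1>\n", html_escape(title)),
         "<div class=\"grid\">\n", paste(cells, collapse = ""),
         "</div>\n</body>\n</html>\n")
}

hex_to_rgb <- function(color) {
  c(strtoi(substr(color, 2, 3), 16L), strtoi(substr(color, 4, 5), 16L),
    strtoi(substr(color, 6, 7), 16L))
}

#' Build a transparent overlay pyramid from a label image
#'
#' Labeled (nonzero) pixels carry the colour at the stated alpha;
#' unlabeled pixels are fully transparent.  The pyramid has exactly the
#' base descriptor's geometry, so the viewer can stack it over the base
#' layer.
#'
#' @param label_image matrix; nonzero marks the region of interest.
#'   Dimensions must equal the base pyramid's.
#' @param color overlay colour (`#rrggbb`).
#' @param base_desc the base pyramid's [dzi_descriptor()].
#' @param out_dir output directory.
#' @param name pyramid name.
#' @param alpha opacity of labeled pixels in `[0, 1]`.
#' @return manifest as from [dzi_build()].
#' @export
build_overlay <- function(label_image, color, base_desc, out_dir,
                          name = "overlay", alpha = 0.35) {
  if (nrow(label_image) != base_desc$height ||
      ncol(label_image) != base_desc$width)
    config_error("label image is %dx%d but base pyramid is %dx%d",
                 ncol(label_image), nrow(label_image),
                 base_desc$width, base_desc$height)
  rgb <- hex_to_rgb(color)
  desc <- dzi_descriptor(base_desc$width, base_desc$height,
                         base_desc$tile_size, base_desc$overlap, "png")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files_dir <- file.path(out_dir, paste0(name, "_files"))
  writeLines(dzi_write_descriptor(desc),
             file.path(out_dir, paste0(name, ".dzi")), sep = "")
  a <- (label_image != 0) * (alpha * 255)
  levels <- data.frame()
  for (level in desc$max_level:0) {
    d <- dzi_level_dims(desc, level)
    g <- dzi_tile_grid(desc, level)
    lvl_dir <- file.path(files_dir, level)
    dir.create(lvl_dir, recursive = TRUE, showWarnings = FALSE)
    aq <- pmin(pmax(round(a), 0), 255)
    for (row in 0:(g[["rows"]] - 1)) for (col in 0:(g[["cols"]] - 1)) {
      rc <- dzi_tile_rect(desc, level, col, row)
      at <- aq[(rc[["y0"]] + 1):rc[["y1"]], (rc[["x0"]] + 1):rc[["x1"]],
               drop = FALSE]
      rgba <- array(0, dim = c(nrow(at), ncol(at), 4))
      rgba[, , 1] <- rgb[1]; rgba[, , 2] <- rgb[2]; rgba[, , 3] <- rgb[3]
      rgba[, , 4] <- at
      write_png(rgba, file.path(lvl_dir, sprintf("%d_%d.png", col, row)))
    }
    levels <- rbind(levels, data.frame(level = level, w = d[["w"]],
                                       h = d[["h"]],
                                       tiles = g[["cols"]] * g[["rows"]]))
    if (level > 0) a <- downsample2(a, box = TRUE)
  }
  levels <- levels[order(levels$level), ]
  rownames(levels) <- NULL
  list(dzi = file.path(out_dir, paste0(name, ".dzi")),
       files_dir = files_dir, levels = levels, n_files = sum(levels$tiles))
}

# Minimal self-authored stand-ins for the vendored viewer scripts.
# They are NOT the real viewer: the published site should replace them
# with the upstream openseadragon + scalebar downloads (see README).
viewer_stub_js <- paste0(
  "/* synthetic placeholder for the vendored deep-zoom viewer script.\n",
  "   Replace this file with the real openseadragon.min.js download;\n",
  "   the atlas generator only writes configuration against its API. */\n",
  "function OpenSeadragon(opts) {\n",
  "  var el = document.getElementById(opts.id);\n",
  "  if (el) { el.setAttribute(\"data-tile-source\", opts.tileSources); }\n",
  "  return {\n",
  "    opts: opts,\n",
  "    scalebar: function (s) {\n",
  "      if (el) { el.setAttribute(\"data-ppm\", String(s.pixelsPerMeter)); }\n",
  "    },\n",
  "    addTiledImage: function (t) { return t; },\n",
  "    world: { getItemAt: function (i) { return undefined; } }\n",
  "  };\n",
  "}\n")

scalebar_stub_js <- paste0(
  "/* synthetic placeholder for the vendored scalebar plug-in.\n",
  "   Replace with the real openseadragon-scalebar.js download. */\n")

#' Write a complete atlas site tree
#'
#' Produces the recipe folder structure: `<site_dir>/index.html`,
#' `<site_dir>/dzi/` (pyramids are expected there) and
#' `<site_dir>/openseadragon/` with placeholder viewer scripts (to be
#' replaced by the real vendored downloads).
#'
#' @param configs list of [viewer_config()] with paths relative to the
#'   site directory (e.g. `dzi/mosaic.dzi`).
#' @param site_dir output directory.
#' @param title page title.
#' @param verify missing pyramids are an error (`TRUE`) or warning.
#' @return path of the written `index.html`, invisibly.
#' @export
write_site <- function(configs, site_dir, title = "EM atlas",
                       verify = TRUE) {
  dir.create(file.path(site_dir, "dzi"), recursive = TRUE,
             showWarnings = FALSE)
  osd <- file.path(site_dir, "openseadragon")
  dir.create(file.path(osd, "images"), recursive = TRUE,
             showWarnings = FALSE)
  stub <- file.path(osd, "openseadragon.min.js")
  if (!file.exists(stub)) writeLines(viewer_stub_js, stub, sep = "")
  sb <- file.path(osd, "openseadragon-scalebar.js")
  if (!file.exists(sb)) writeLines(scalebar_stub_js, sb, sep = "")
  html <- render_page(configs, title, base_dir = site_dir, verify = verify)
  out <- file.path(site_dir, "index.html")
  writeLines(html, out, sep = "")
  invisible(out)
}
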