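#' Run the full canopy phenotyping pipeline on an image directory
#'
#' Binds the modules end to end: every tray image in `images_dir` matching
#' `pattern` is segmented, split into containers and measured with the
#' line descent; heights are assembled into per-container growth curves;
#' the separation day is detected and the drought/recovery traits are
#' extracted per tray; optional fluorescence traces are converted to
#' quenching yields. All outputs are written as CSV into `out_dir`
#' together with a JSON manifest (configuration, file list, package
#' version), and the run is deterministic for identical inputs and
#' configuration.
#'
#' Unreadable images are reported as warnings and skipped (the run
#' continues); a container without vegetation yields a `no_plant`-flagged
#' row. Missing days are left as gaps — no interpolation is performed.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{images_dir}{directory of tray images named
#'       `tray<ID>_day<D>.png` (or `.tif`); the naming regex can be
#'       overridden with `pattern` (two capture groups: tray, day).}
#'     \item{layout}{a [tray_layout()] or path to a layout YAML.}
#'     \item{tau}{line-descent threshold (default 0.2).}
#'     \item{segmentation}{list: `method`, `threshold`,
#'       `min_component_px`.}
#'     \item{variants}{list mapping containers to variants, default
#'       `list(left = "D", right = "W")`.}
#'     \item{kinetics}{list: `rule`, `delta`, `rewater_day`, `end_day`
#'       (rewater_day required for trait extraction).}
#'     \item{fluor_csv}{optional CSV of fluorescence traces with columns
#'       `F0, FM, Ft, FMprime` (+ optional `F0prime` and annotations).}
#'     \item{out_dir}{output directory (created if needed).}
#'   }
#' @return Invisibly, a list with data frames `heights`, `traits`,
#'   `yields` (NULL when no fluorescence input) and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$images_dir) || !dir.exists(config$images_dir))
    stop_invalid_input("config$images_dir must name an existing directory")
  if (is.null(config$out_dir)) stop_invalid_input("config$out_dir is required")
  layout <- config$layout
  if (is.character(layout)) layout <- read_tray_layout(layout)
  if (!inherits(layout, "tray_layout")) {
    if (is.list(layout))
      layout <- tray_layout(layout$split_column, unlist(layout$left_roi),
                            unlist(layout$right_roi), layout$soil_row)
    else stop_invalid_input("config$layout must be a tray_layout or a path")
  }
  tau <- config$tau %||% 0.2
  seg <- config$segmentation %||% list()
  variants <- config$variants %||% list(left = "D", right = "W")
  pattern <- config$pattern %||% "^tray([A-Za-z0-9]+)_day([0-9]+)\\.(png|tif|tiff)$"

  files <- sort(list.files(config$images_dir, full.names = FALSE))
  files <- files[grepl(pattern, files)]
  if (!length(files))
    stop_invalid_input(sprintf("no images matching '%s' in %s",
                               pattern, config$images_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  read_failures <- character(0)
  for (f in files) {
    tray <- sub(pattern, "\\1", f)
    day <- as.integer(sub(pattern, "\\2", f))
    px <- tryCatch(read_rgb_image(file.path(config$images_dir, f)),
                   error = function(e) {
                     warning(sprintf("skipping unreadable image %s: %s",
                                     f, conditionMessage(e)), call. = FALSE)
                     NULL
                   })
    if (is.null(px)) { read_failures <- c(read_failures, f); next }
    hr <- heights_for_tray(px, layout, tau = tau,
                           method = seg$method %||% "excess_green_otsu",
                           threshold = seg$threshold,
                           min_component_px = seg$min_component_px %||% 12)
    for (side in c("left", "right")) {
      r <- hr[[side]]
      rows[[length(rows) + 1L]] <- data.frame(
        tray_id = tray, day = day, container = side,
        variant = variants[[side]] %||% NA_character_,
        stop_row = r$stop_row, height_px = r$height_px,
        flag = ifelse(is.na(r$flag), "", r$flag))
    }
  }
  heights <- do.call(rbind, rows)
  heights <- heights[order(heights$tray_id, heights$day, heights$container), ]
  utils::write.csv(heights, file.path(config$out_dir, "heights.csv"),
                   row.names = FALSE)

  traits <- NULL
  kin <- config$kinetics %||% list()
  if (!is.null(kin$rewater_day)) {
    ok <- heights$flag == "" & !is.na(heights$height_px)
    h <- heights[ok, ]
    Wv <- h[h$variant == "W", c("day", "height_px")]
    Dv <- h[h$variant == "D", c("day", "height_px")]
    sep_day <- tryCatch(
      detect_separation_day(Wv, Dv, rule = kin$rule %||% "auto",
                            delta = kin$delta %||% 0.10),
      canopydyn_error = function(e) {
        warning(paste("separation-day detection failed:",
                      conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(sep_day)) {
      tlist <- list()
      for (tr in unique(h$tray_id)) {
        cv <- h[h$tray_id == tr & h$variant == "D", ]
        cv <- stats::aggregate(height_px ~ day, cv, mean)
        st <- tryCatch(
          extract_stress_traits(cv, sep_day, kin$rewater_day,
                                kin$end_day %||% max(cv$day)),
          canopydyn_error = function(e) NULL)
        if (!is.null(st))
          tlist[[length(tlist) + 1L]] <-
            cbind(data.frame(tray_id = tr, separation_rule = attr(sep_day, "rule")), st)
      }
      if (length(tlist)) {
        traits <- do.call(rbind, tlist)
        utils::write.csv(traits, file.path(config$out_dir, "traits.csv"),
                         row.names = FALSE)
      }
    }
  }

  yields <- NULL
  if (!is.null(config$fluor_csv)) {
    tr <- utils::read.csv(config$fluor_csv)
    need <- c("F0", "FM", "Ft", "FMprime")
    if (!all(need %in% names(tr)))
      stop_invalid_input("fluor_csv must have columns F0, FM, Ft, FMprime")
    ys <- lapply(seq_len(nrow(tr)), function(i) {
      y <- quenching_yields(fluor_trace(
        F0 = tr$F0[i], FM = tr$FM[i], Ft = tr$Ft[i], FMprime = tr$FMprime[i],
        F0prime = if ("F0prime" %in% names(tr) && !is.na(tr$F0prime[i]))
          tr$F0prime[i]))
      as.data.frame(y[c("phi_Po", "phi_PSII", "qP", "phi_P", "phi_NPQ",
                        "phi_fD", "F0prime_source")])
    })
    ann <- tr[, setdiff(names(tr), c(need, "F0prime")), drop = FALSE]
    yields <- cbind(ann, do.call(rbind, ys))
    utils::write.csv(yields, file.path(config$out_dir, "yields.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "canopydyn",
    version = as.character(utils::packageVersion("canopydyn")),
    images = files, skipped = read_failures,
    tau = tau, segmentation = seg, variants = variants,
    layout = lapply(unclass(layout), as.integer),
    kinetics = kin)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (length(read_failures))
    warning(sprintf("%d image(s) could not be read", length(read_failures)),
            call. = FALSE)
  invisible(list(heights = heights, traits = traits, yields = yields,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
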