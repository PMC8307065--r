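# Artifact writers: float-TIFF fields, paletted segmentation PNG, CSV
# summaries with a config-hash header, JSON report.

#' Write a scalar field as 32-bit float TIFF
#'
#' @param field Numeric matrix (`NA` allowed; stored as-is).
#' @param path Output `.tif`/`.tiff` path.
#' @return `path` invisibly.
#' @export
write_field_tiff <- function(field, path) {
  tiff::writeTIFF(field, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

# class -> RGB used for the segmentation PNG
.seg_palette <- list(
  physoxia = c(0.85, 0.10, 0.10),
  physiological_hypoxia = c(0.10, 0.70, 0.10),
  pathological_hypoxia = c(0.15, 0.25, 0.85),
  radiobiological_hypoxia = c(0.05, 0.05, 0.05),
  vessel = c(1.00, 1.00, 1.00)
)

#' Write a tissue segmentation as a colored PNG
#'
#' Physoxia red, physiological hypoxia green, pathological hypoxia blue,
#' radiobiological hypoxia black, vessels white.
#'
#' @param seg A [segment_tissue()] result.
#' @param path Output `.png` path.
#' @return `path` invisibly.
#' @export
write_segmentation_png <- function(seg, path) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  lab <- seg$labels
  img <- array(0, c(nrow(lab), ncol(lab), 3))
  for (cl in names(.seg_palette)) {
    sel <- !is.na(lab) & lab == cl
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[sel] <- .seg_palette[[cl]][ch]; img[, , ch] <- pl
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

# 32-bit polynomial hash of a config's YAML serialization: a compact
# provenance stamp embedded in artifact headers.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  bytes <- as.integer(charToRaw(paste(readLines(tmp), collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

write_csv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# One ROI's artifact set under out_dir.
write_roi_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(report$config)
  write_vessel_mask(report$map, file.path(out_dir, "vessel_mask.png"))
  P <- report$oxygen$P
  P[is.na(P)] <- 0
  write_field_tiff(P / max(P), file.path(out_dir, "po2_norm.tif"))
  write_segmentation_png(report$segmentation,
                         file.path(out_dir, "segmentation.png"))
  write_csv_stamped(
    data.frame(metric = c("vascular_fraction", "median_po2",
                          names(report$class_fractions)),
               value = c(report$vascular_fraction, report$median_po2,
                         unname(report$class_fractions))),
    file.path(out_dir, "oxygenation_summary.csv"), hash)
  for (nuc in names(report$nuclides)) {
    pn <- report$nuclides[[nuc]]
    Dn <- pn$dose$D / max(pn$dose$D, 1e-300)
    write_field_tiff(Dn, file.path(out_dir, sprintf("dose_norm_%s.tif", nuc)))
    write_csv_stamped(pn$dth$table,
                      file.path(out_dir, sprintf("dth_%s.csv", nuc)), hash)
    write_csv_stamped(pn$survival$class_summary,
                      file.path(out_dir, sprintf("survival_%s.csv", nuc)),
                      hash)
  }
  jsonlite::write_json(
    roi_report_summary(report, hash),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

# JSON-serializable summary of an roi_report
roi_report_summary <- function(report, hash = config_hash(report$config)) {
  list(
    config_hash = hash,
    vascular_fraction = report$vascular_fraction,
    median_po2 = report$median_po2,
    class_fractions = as.list(report$class_fractions),
    nuclides = lapply(report$nuclides, function(pn) {
      list(
        injected_scale = pn$injected_scale,
        mean_dose_Gy = unname(pn$dose_stats[["mean"]]),
        sd_dose_Gy = unname(pn$dose_stats[["sd"]]),
        fraction_at_target = as.list(pn$fraction_at_target),
        mean_PS = pn$survival$mean,
        sd_PS = pn$survival$sd
      )
    })
  )
}
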