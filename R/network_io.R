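#' Read an arterial network from its tabular on-disk format
#'
#' The network file is CSV with one row per vessel and columns `id`,
#' `parent_ids` (semicolon separated), `length_mm`, `r_prox_mm`,
#' `r_dist_mm`, `h0_mm`, `E_kPa`, `nu`, `role_tag`, `outlet_R_total`
#' (1e10 Pa s/m^3, empty for internal vessels), `outlet_C`
#' (1e-10 m^3/Pa), `outlet_r1_frac` (empty for the characteristic-impedance
#' rule) and `outlet_p_out_Pa`.  A probes file (`name`, `vessel_id`,
#' `axial_fraction`) and a JSON metadata sidecar are read when present.
#'
#' @param path path to the network CSV.
#' @param probes_path path to the probes CSV; defaults to
#'   `<path minus .csv>_probes.csv` if that file exists.
#' @param metadata_path path to the JSON sidecar; defaults to
#'   `<path minus .csv>_meta.json` if that file exists.
#' @return a validated [arterial_network()].
#' @export
read_network <- function(path, probes_path = NULL, metadata_path = NULL) {
  stem <- sub("\\.csv$", "", path)
  if (is.null(probes_path)) {
    cand <- paste0(stem, "_probes.csv")
    probes_path <- if (file.exists(cand)) cand else NA_character_
  }
  if (is.null(metadata_path)) {
    cand <- paste0(stem, "_meta.json")
    metadata_path <- if (file.exists(cand)) cand else NA_character_
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$id <- as.character(d$id)
  d$parent_ids <- as.character(d$parent_ids)
  need <- c("id", "parent_ids", "length_mm", "r_prox_mm", "r_dist_mm",
            "h0_mm", "E_kPa", "nu", "role_tag", "outlet_R_total", "outlet_C")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("network file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  d$parent_ids[is.na(d$parent_ids)] <- ""
  num <- c("length_mm", "r_prox_mm", "r_dist_mm", "h0_mm", "E_kPa", "nu")
  for (cn in num) {
    v <- d[[cn]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      stop(sprintf("network file %s: non-numeric or missing %s in row %d (vessel %s)",
                   path, cn, which(is.na(v))[1], d$id[which(is.na(v))[1]]))
    }
    d[[cn]] <- v
  }
  vessels <- data.frame(id = d$id, parent_ids = d$parent_ids,
                        length = d$length_mm / 1000,
                        r_prox = d$r_prox_mm / 1000,
                        r_dist = d$r_dist_mm / 1000,
                        h0 = d$h0_mm / 1000,
                        E = d$E_kPa * 1000,
                        nu = d$nu, role_tag = d$role_tag,
                        stringsAsFactors = FALSE)
  has_out <- !is.na(suppressWarnings(as.numeric(d$outlet_R_total)))
  r1f <- if ("outlet_r1_frac" %in% names(d)) {
    suppressWarnings(as.numeric(d$outlet_r1_frac))
  } else rep(NA_real_, nrow(d))
  pout <- if ("outlet_p_out_Pa" %in% names(d)) {
    suppressWarnings(as.numeric(d$outlet_p_out_Pa))
  } else rep(0, nrow(d))
  pout[is.na(pout)] <- 0
  outlets <- data.frame(vessel_id = d$id[has_out],
                        R_total = as.numeric(d$outlet_R_total[has_out]) * 1e10,
                        C = as.numeric(d$outlet_C[has_out]) * 1e-10,
                        r1_frac = r1f[has_out],
                        p_out = pout[has_out],
                        stringsAsFactors = FALSE)
  probes <- NULL
  if (!is.na(probes_path)) {
    p <- utils::read.csv(probes_path, stringsAsFactors = FALSE)
    probes <- data.frame(name = as.character(p$name),
                         vessel_id = as.character(p$vessel_id),
                         frac = as.numeric(p$axial_fraction),
                         stringsAsFactors = FALSE)
  }
  metadata <- list()
  if (!is.na(metadata_path)) {
    metadata <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  }
  net <- arterial_network(vessels, outlets, probes, metadata, check = FALSE)
  f <- validate_network(net)
  if (length(f)) {
    stop("network file ", path, " is invalid:\n  ", paste(f, collapse = "\n  "))
  }
  net
}

#' Write an arterial network to the tabular on-disk format
#'
#' Inverse of [read_network()]; `read_network(write_network(net, path))`
#' reproduces the network field-for-field (to full double precision).
#'
#' @param net an `arterial_network`.
#' @param path output CSV path; the probes file and JSON metadata sidecar
#'   are written next to it with `_probes.csv` / `_meta.json` suffixes.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  v <- net$vessels
  idx <- match(v$id, net$outlets$vessel_id)
  fmt <- function(x) vapply(x, function(e)
    if (is.na(e)) "" else format(e, digits = 17, scientific = FALSE), "")
  d <- data.frame(id = v$id, parent_ids = v$parent_ids,
                  length_mm = fmt(v$length * 1000),
                  r_prox_mm = fmt(v$r_prox * 1000),
                  r_dist_mm = fmt(v$r_dist * 1000),
                  h0_mm = fmt(v$h0 * 1000),
                  E_kPa = fmt(v$E / 1000),
                  nu = fmt(v$nu),
                  role_tag = v$role_tag,
                  outlet_R_total = fmt(net$outlets$R_total[idx] / 1e10),
                  outlet_C = fmt(net$outlets$C[idx] / 1e-10),
                  outlet_r1_frac = fmt(net$outlets$r1_frac[idx]),
                  outlet_p_out_Pa = fmt(net$outlets$p_out[idx]),
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  stem <- sub("\\.csv$", "", path)
  p <- data.frame(name = net$probes$name, vessel_id = net$probes$vessel_id,
                  axial_fraction = fmt(net$probes$frac))
  utils::write.csv(p, paste0(stem, "_probes.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(net$metadata, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
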