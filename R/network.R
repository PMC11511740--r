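#' Arterial network container
#'
#' An `arterial_network` bundles the vessel table, outlet lumped models,
#' measurement probes and the inlet designation.  All fields are SI
#' internally (m, Pa, Pa s/m^3, m^3/Pa); the on-disk format uses the
#' clinical units of the printed tables (mm, kPa, 1e10 Pa s/m^3,
#' 1e-10 m^3/Pa), see [read_network()].
#'
#' @param vessels data.frame with columns `id`, `parent_ids` (semicolon
#'   separated, empty for the inlet vessel), `length`, `r_prox`, `r_dist`,
#'   `h0` (m), `E` (Pa), `nu`, `role_tag` (one of `systemic`, `renal_main`,
#'   `renal_segmental`, `renal_interlobar`).
#' @param outlets data.frame with columns `vessel_id`, `R_total` (Pa s/m^3),
#'   `C` (m^3/Pa), `r1_frac` (proximal resistance fraction in \[0,1), or NA
#'   for the characteristic-impedance rule), `p_out` (Pa).
#' @param probes data.frame with columns `name`, `vessel_id`, `frac`
#'   (fractional axial position in \[0,1\]).
#' @param metadata named list; fixture counts (`n_vessels`, `n_outlets`,
#'   `n_renal_per_side`) are asserted by [validate_network()] when present.
#' @param check validate on construction and stop on findings.
#' @return an object of class `arterial_network`.
#' @export
arterial_network <- function(vessels, outlets, probes = NULL,
                             metadata = list(), check = TRUE) {
  if (is.null(probes)) {
    probes <- data.frame(name = character(), vessel_id = character(),
                         frac = numeric(), stringsAsFactors = FALSE)
  }
  vessels$id <- as.character(vessels$id)
  vessels$parent_ids <- as.character(vessels$parent_ids)
  roots <- vessels$id[vessels$parent_ids == ""]
  net <- structure(list(vessels = vessels, outlets = outlets, probes = probes,
                        inlet_vessel_id = if (length(roots)) roots[[1]] else NA_character_,
                        metadata = metadata),
                   class = "arterial_network")
  if (check) {
    f <- validate_network(net)
    if (length(f)) stop("invalid network:\n  ", paste(f, collapse = "\n  "))
  }
  net
}

#' @export
print.arterial_network <- function(x, ...) {
  nr <- sum(x$vessels$role_tag != "systemic")
  cat(sprintf(paste0("<arterial_network> %d vessels (%d renal), %d outlets, ",
                     "%d probes, inlet: %s\n"),
              nrow(x$vessels), nr, nrow(x$outlets), nrow(x$probes),
              x$inlet_vessel_id))
  invisible(x)
}

# split a semicolon-joined parent field into a character vector
.split_parents <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Children lookup for every vessel
#'
#' @param net an `arterial_network`.
#' @return named list mapping each vessel id to the character vector of its
#'   child vessel ids (possibly empty).
#' @export
network_children <- function(net) {
  ids <- net$vessels$id
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) out[[i]] <- character()
  for (i in seq_len(nrow(net$vessels))) {
    for (p in .split_parents(net$vessels$parent_ids[i])) {
      if (p %in% ids) out[[p]] <- c(out[[p]], ids[i])
    }
  }
  out
}

#' Junction list of a network
#'
#' Each junction couples the distal end of one (or more) parent vessels to
#' the proximal ends of their children.
#'
#' @param net an `arterial_network`.
#' @return list of `list(parent_ids, child_ids)`.
#' @export
network_junctions <- function(net) {
  ch <- network_children(net)
  keep <- vapply(ch, length, 1L) > 0
  lapply(names(ch)[keep], function(p)
    list(parent_ids = p, child_ids = ch[[p]]))
}

#' Structural validation of an arterial network
#'
#' Checks the invariants of the data model: positive geometry, Poisson
#' ratio in (0,1), distal taper, referenced parents exist, a unique inlet,
#' reachability of every vessel from the inlet, consistency of terminal
#' vessels with the outlet table, positive outlet parameters, probe
#' references, and any counts recorded in the metadata.
#'
#' @param net an `arterial_network`.
#' @return character vector of human-readable findings; empty if the
#'   network is valid.
#' @export
validate_network <- function(net) {
  f <- character()
  v <- net$vessels
  if (anyDuplicated(v$id)) {
    f <- c(f, sprintf("duplicate vessel id: %s",
                      paste(unique(v$id[duplicated(v$id)]), collapse = ", ")))
  }
  bad <- function(cond, msg) {
    if (any(cond)) sprintf(msg, paste(v$id[cond], collapse = ", ")) else character()
  }
  f <- c(f, bad(v$length <= 0, "non-positive length: %s"))
  f <- c(f, bad(v$r_prox <= 0 | v$r_dist <= 0, "non-positive radius: %s"))
  f <- c(f, bad(v$h0 <= 0, "non-positive wall thickness: %s"))
  f <- c(f, bad(v$E <= 0, "non-positive Young's modulus: %s"))
  f <- c(f, bad(v$nu <= 0 | v$nu >= 1, "Poisson ratio outside (0,1): %s"))
  f <- c(f, bad(v$r_dist > v$r_prox * (1 + 1e-12), "distal radius exceeds proximal: %s"))
  tags <- c("systemic", "renal_main", "renal_segmental", "renal_interlobar")
  f <- c(f, bad(!(v$role_tag %in% tags), "unknown role_tag: %s"))

  roots <- v$id[v$parent_ids == ""]
  if (length(roots) != 1) {
    f <- c(f, sprintf("expected exactly one inlet vessel, found %d (%s)",
                      length(roots), paste(roots, collapse = ", ")))
  }
  for (i in seq_len(nrow(v))) {
    miss <- setdiff(.split_parents(v$parent_ids[i]), v$id)
    if (length(miss)) {
      f <- c(f, sprintf("vessel %s references unknown parent %s",
                        v$id[i], paste(miss, collapse = ", ")))
    }
  }
  # reachability from the inlet
  if (length(roots) >= 1) {
    ch <- network_children(net)
    seen <- roots[[1]]
    frontier <- roots[[1]]
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(ch[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    orphan <- setdiff(v$id, seen)
    if (length(orphan)) {
      f <- c(f, sprintf("vessel(s) not reachable from the inlet: %s",
                        paste(orphan, collapse = ", ")))
    }
    # terminal vessels must have an outlet, internal vessels must not
    terminals <- v$id[vapply(ch[v$id], length, 1L) == 0]
    no_out <- setdiff(terminals, net$outlets$vessel_id)
    if (length(no_out)) {
      f <- c(f, sprintf("terminal vessel(s) without outlet model: %s",
                        paste(no_out, collapse = ", ")))
    }
    extra <- setdiff(net$outlets$vessel_id, terminals)
    if (length(extra)) {
      f <- c(f, sprintf("outlet attached to non-terminal vessel: %s",
                        paste(extra, collapse = ", ")))
    }
  }
  o <- net$outlets
  if (nrow(o)) {
    if (any(o$R_total <= 0)) f <- c(f, "non-positive outlet resistance")
    if (any(o$C < 0)) f <- c(f, "negative outlet compliance")
    rf <- o$r1_frac[!is.na(o$r1_frac)]
    if (any(rf < 0 | rf >= 1)) f <- c(f, "proximal resistance fraction outside [0,1)")
  }
  if (nrow(net$probes)) {
    miss <- setdiff(net$probes$vessel_id, v$id)
    if (length(miss)) {
      f <- c(f, sprintf("probe references unknown vessel: %s",
                        paste(miss, collapse = ", ")))
    }
    if (any(net$probes$frac < 0 | net$probes$frac > 1)) {
      f <- c(f, "probe axial fraction outside [0,1]")
    }
  }
  m <- net$metadata
  if (!is.null(m$n_vessels) && m$n_vessels != nrow(v)) {
    f <- c(f, sprintf("metadata records %d vessels, network has %d",
                      m$n_vessels, nrow(v)))
  }
  if (!is.null(m$n_outlets) && m$n_outlets != nrow(o)) {
    f <- c(f, sprintf("metadata records %d outlets, network has %d",
                      m$n_outlets, nrow(o)))
  }
  if (!is.null(m$n_renal_per_side)) {
    for (side in c("L", "R")) {
      n <- sum(v$role_tag != "systemic" & grepl(paste0("_", side, "($|[0-9_])"),
                                                v$id))
      if (n != m$n_renal_per_side) {
        f <- c(f, sprintf("metadata records %d renal vessels per side, side %s has %d",
                          m$n_renal_per_side, side, n))
      }
    }
  }
  f
}
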