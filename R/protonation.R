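# Ionization-state enumeration over a pH window. Each ionizable site is
# located by a substructure pattern from a curated table carrying a literature
# mean pKa and spread; at a given window [min_ph, max_ph] with precision d
# the site is emitted deprotonated when pKa - d < max_ph, protonated when
# pKa + d > min_ph, and in both forms when both hold. Highly charged
# combinations are pruned relative to the form whose net charge is closest
# to zero.

#' Load the ionizable-site table
#'
#' @param path optional path to a user table (same JSON schema as the
#'   packaged one: name, smarts, site, mean_pka, pka_sd, prot_charge,
#'   deprot_charge).
#' @return list of site definitions with pre-parsed patterns
#' @export
load_site_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ionizable_sites.json", package = "molprep")
    if (!nzchar(path)) path <- file.path("inst", "extdata", "ionizable_sites.json")
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(e) {
    stopifnot(e$pka_sd >= 0)
    e$pattern <- parse_smarts(e$smarts)
    e
  })
}

.site_table_cache <- new.env(parent = emptyenv())
default_site_table <- function() {
  if (is.null(.site_table_cache$tab)) .site_table_cache$tab <- load_site_table()
  .site_table_cache$tab
}

# Find ionizable sites: table entries are tried in order and the first entry
# claiming an atom wins.
find_ionizable_sites <- function(g, table = default_site_table()) {
  claimed <- rep(FALSE, n_atoms(g))
  sites <- list()
  for (e in table) {
    for (m in smarts_match_all(g, e$pattern)) {
      atom <- m[[e$site]]
      if (claimed[atom]) next
      claimed[atom] <- TRUE
      sites[[length(sites) + 1L]] <- list(atom = atom, entry = e)
    }
  }
  sites
}

#' Enumerate ionization states over a pH window
#'
#' @param g mol_graph (desalted)
#' @param min_ph,max_ph window bounds (defaults 6.4 and 8.4)
#' @param pka_precision symmetric +/- window around each site pKa (default 1)
#' @param parent_id identifier recorded on the emitted variants
#' @param site_table optional table from [load_site_table()]
#' @param cap maximum number of emitted combinations (default 128)
#' @return list of [variant()]s; the input itself (single variant, no
#'   provenance) when no site matches
#' @export
enumerate_ionization_states <- function(g, min_ph = 6.4, max_ph = 8.4,
                                        pka_precision = 1.0, parent_id = "",
                                        site_table = NULL, cap = 128L) {
  stopifnot(min_ph <= max_ph, pka_precision >= 0)
  table <- if (is.null(site_table)) default_site_table() else site_table
  sites <- find_ionizable_sites(g, table)
  if (!length(sites)) return(list(variant(parent_id, g)))

  # allowed states per site: list of target charges with labels
  site_states <- lapply(sites, function(s) {
    e <- s$entry
    states <- list()
    if (e$mean_pka - pka_precision < max_ph)
      states <- c(states, list(list(charge = e$deprot_charge, label = "deprotonated")))
    if (e$mean_pka + pka_precision > min_ph)
      states <- c(states, list(list(charge = e$prot_charge, label = "protonated")))
    if (!length(states))
      states <- list(list(charge = g$atoms$charge[s$atom], label = "unchanged"))
    states
  })

  combos <- expand.grid(lapply(site_states, seq_along))
  if (nrow(combos) > cap) {
    warning(sprintf("ionization combinations truncated at cap = %d", cap))
    combos <- combos[seq_len(cap), , drop = FALSE]
  }
  out <- list()
  for (r in seq_len(nrow(combos))) {
    g2 <- g
    details <- character(0)
    ok <- TRUE
    for (j in seq_along(sites)) {
      s <- sites[[j]]
      st <- site_states[[j]][[combos[r, j]]]
      delta <- st$charge - g2$atoms$charge[s$atom]
      newh <- g2$atoms$hcount[s$atom] + delta
      if (newh < 0L) { ok <- FALSE; break }
      g2$atoms$hcount[s$atom] <- newh
      g2$atoms$charge[s$atom] <- st$charge
      details <- c(details, sprintf("%s at atom %d: %s",
                                    s$entry$name, s$atom, st$label))
    }
    if (!ok) next
    valid <- tryCatch({ validate_valences(g2, "<ionization>"); TRUE },
                      error = function(e) FALSE)
    if (!valid) next
    v <- variant(parent_id, g2)
    v <- add_provenance(v, "ionize", paste(details, collapse = "; "))
    out[[length(out) + 1L]] <- v
  }
  if (!length(out)) return(list(variant(parent_id, g)))
  dedupe_variants(out)
}

#' Prune ionization variants by formal charge
#'
#' Finds the variant whose net formal charge is closest to zero (ties go to
#' the more negative candidate) and eliminates every variant whose charge
#' deviates from that baseline by 3 e or more, i.e. retains |q - q0| <= 2.
#'
#' @param variants non-empty list of [variant()]s
#' @return filtered list (always non-empty)
#' @export
prune_by_formal_charge <- function(variants) {
  stopifnot(length(variants) > 0)
  q <- vapply(variants, function(v) net_formal_charge(v$graph), integer(1))
  aq <- abs(q)
  cand <- q[aq == min(aq)]
  q0 <- min(cand)  # tie: more negative baseline
  keep <- abs(q - q0) <= 2L
  variants[keep]
}
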