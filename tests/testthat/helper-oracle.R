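# Brute-force expansion oracle, independent of the expander: it tries
# EVERY full state combination of every reactant occurrence and filters
# by pattern membership, resolving products with its own index
# arithmetic on the label vectors. Used to cross-check expand_reaction
# on randomly generated small models.

oracle_statelist <- function(site, model) {
  if (identical(site$kind, "enumset")) return(site$labels)
  if (identical(site$kind, "empty")) return(character())
  lo <- evaluate_static(site$lo, model$globals)
  hi <- evaluate_static(site$hi, model$globals)
  if (lo > hi) character() else as.character(lo:hi)
}

oracle_site <- function(model, species, site_name) {
  for (s in model$species[[species]]$sites) {
    if (s$name == site_name) return(s)
  }
  NULL
}

oracle_admits <- function(pat, label, labels, model) {
  if (is.null(pat) || pat$kind == "any") return(TRUE)
  if (pat$kind == "fixed") return(label == pat$label)
  if (pat$kind == "enumset") return(label %in% pat$labels)
  if (pat$kind == "range") {
    v <- as.numeric(label)
    !is.na(v) &&
      v >= evaluate_static(pat$lo, model$globals) &&
      v <= evaluate_static(pat$hi, model$globals)
  } else {
    FALSE
  }
}

oracle_step <- function(labels, circular, label, dir) {
  i <- match(label, labels) + dir
  n <- length(labels)
  if (i < 1 || i > n) {
    if (!circular) stop("oracle: operator out of range")
    i <- ((i - 1) %% n) + 1
  }
  labels[[i]]
}

# name building mirrors the documented naming scheme (it is part of the
# contract being checked)
oracle_name <- function(base, sites, labels) {
  if (length(sites) == 0) return(base)
  paste(c(base, gsub("[^A-Za-z0-9_]", "_", paste0(sites, labels))),
        collapse = "_")
}

# returns a sorted character vector of canonical flat-reaction strings
oracle_expand <- function(rxn, model) {
  slot_sites <- list()   # per reactant occurrence: site name vector
  slot_labels <- list()  # per (occ, site): full label list
  occ_site_names <- list()
  for (i in seq_along(rxn$reactants)) {
    ref <- rxn$reactants[[i]]
    sp <- model$species[[ref$species]]
    occ_site_names[[i]] <- vapply(sp$sites, `[[`, "", "name")
    for (s in sp$sites) {
      slot_labels[[length(slot_labels) + 1L]] <-
        list(occ = i, site = s$name, labels = oracle_statelist(s, model))
    }
  }
  grids <- lapply(slot_labels, `[[`, "labels")
  combos <- if (length(grids) == 0) list(integer(0)) else {
    g <- do.call(expand.grid, c(lapply(grids, seq_along),
                                list(KEEP.OUT.ATTRS = FALSE,
                                     stringsAsFactors = FALSE)))
    lapply(seq_len(nrow(g)), function(r) unlist(g[r, ], use.names = FALSE))
  }
  out <- character()
  for (combo in combos) {
    assignment <- lapply(seq_along(rxn$reactants), function(i) character())
    ok <- TRUE
    for (j in seq_along(slot_labels)) {
      sl <- slot_labels[[j]]
      label <- sl$labels[[combo[[j]]]]
      ref <- rxn$reactants[[sl$occ]]
      if (!oracle_admits(ref$patterns[[sl$site]], label, sl$labels, model)) {
        ok <- FALSE
        break
      }
      assignment[[sl$occ]][[sl$site]] <- label
    }
    if (!ok) next
    source_label <- function(species, site) {
      for (i in seq_along(rxn$reactants)) {
        if (rxn$reactants[[i]]$species == species) return(assignment[[i]][[site]])
      }
      stop("oracle: no source reactant")
    }
    reactant_names <- vapply(seq_along(rxn$reactants), function(i) {
      ref <- rxn$reactants[[i]]
      sn <- occ_site_names[[i]]
      oracle_name(ref$species, sn,
                  vapply(sn, function(s) assignment[[i]][[s]], ""))
    }, character(1))
    product_names <- vapply(rxn$products, function(ref) {
      sp <- model$species[[ref$species]]
      sn <- vapply(sp$sites, `[[`, "", "name")
      labs <- vapply(sn, function(s) {
        pat <- ref$patterns[[s]]
        site <- oracle_site(model, ref$species, s)
        labels <- oracle_statelist(site, model)
        if (is.null(pat) || pat$kind == "any") {
          source_label(ref$species, s)
        } else if (pat$kind == "fixed") {
          pat$label
        } else if (pat$kind == "opcall") {
          oracle_step(labels, isTRUE(site$circular),
                      source_label(ref$species, pat$site),
                      if (pat$op == "succ") 1L else -1L)
        } else if (pat$kind == "transfer") {
          src_site <- oracle_site(model, pat$src_species, pat$src_site)
          src_labels <- oracle_statelist(src_site, model)
          lab <- source_label(pat$src_species, pat$src_site)
          if (is.null(pat$op)) lab
          else oracle_step(src_labels, isTRUE(src_site$circular), lab,
                           if (pat$op == "succ") 1L else -1L)
        } else {
          stop("oracle: bad product pattern")
        }
      }, character(1))
      oracle_name(ref$species, sn, labs)
    }, character(1))
    out <- c(out, paste(paste(sort(reactant_names), collapse = "+"),
                        paste(sort(product_names), collapse = "+"),
                        sep = ">"))
  }
  sort(out)
}

canonical_flat <- function(flat_reactions) {
  sort(vapply(flat_reactions, function(fr) {
    paste(paste(sort(fr$reactants), collapse = "+"),
          paste(sort(fr$products), collapse = "+"), sep = ">")
  }, character(1)))
}

# ------------------------------------------------- random model generator

# Small random multistate models: <= 3 sites, <= 5 states per site,
# mixed integer ranges / enumerated (possibly symbolic, possibly
# circular) state lists, one reaction with random reactant patterns and
# random product resolution (carry / fixed / succ / pred), sometimes a
# zero-site catalyst. Always valid by construction (operators are only
# applied where the admitted states stay clear of the boundary, unless
# the list is circular).
random_model <- function() {
  n_sites <- sample(1:3, 1)
  site_defs <- character(n_sites)
  site_info <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    nm <- paste0("s", s)
    if (runif(1) < 0.5) {
      k <- sample(0:4, 1)
      labels <- as.character(0:k)
      circ <- FALSE
      site_defs[[s]] <- sprintf("%s{0:%d}", nm, k)
    } else {
      n_lab <- sample(1:5, 1)
      pool <- if (runif(1) < 0.5) as.character(sample(0:9, n_lab)) else
        paste0("st", sample(letters, n_lab))
      labels <- pool
      circ <- runif(1) < 0.25
      site_defs[[s]] <- sprintf("%s{%s}%s", nm, paste(labels, collapse = ","),
                                if (circ) "~circ" else "")
    }
    site_info[[s]] <- list(name = nm, labels = labels, circ = circ)
  }
  with_catalyst <- runif(1) < 0.4
  reactant_pats <- character(n_sites)
  admitted <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    info <- site_info[[s]]
    u <- runif(1)
    if (u < 0.3) {
      reactant_pats[[s]] <- info$name  # unconstrained
      admitted[[s]] <- info$labels
    } else if (u < 0.55) {
      lab <- sample(info$labels, 1)
      reactant_pats[[s]] <- sprintf("%s{%s}", info$name, lab)
      admitted[[s]] <- lab
    } else {
      idx <- sort(sample(seq_along(info$labels),
                         sample(seq_along(info$labels), 1)))
      labs <- info$labels[idx]
      numeric <- !anyNA(suppressWarnings(as.numeric(info$labels)))
      if (numeric && runif(1) < 0.6) {
        vals <- as.numeric(info$labels)
        lo <- min(as.numeric(labs)); hi <- max(as.numeric(labs))
        reactant_pats[[s]] <- sprintf("%s{%s:%s}", info$name, lo, hi)
        admitted[[s]] <- info$labels[vals >= lo & vals <= hi]
      } else {
        reactant_pats[[s]] <- sprintf("%s{%s}", info$name,
                                      paste(labs, collapse = ","))
        admitted[[s]] <- labs
      }
    }
  }
  product_pats <- character(0)
  for (s in seq_len(n_sites)) {
    info <- site_info[[s]]
    adm <- admitted[[s]]
    n <- length(info$labels)
    can_succ <- info$circ || !(info$labels[[n]] %in% adm)
    can_pred <- info$circ || !(info$labels[[1]] %in% adm)
    choices <- c("carry", "fixed", if (can_succ) "succ", if (can_pred) "pred")
    ch <- sample(choices, 1)
    pat <- switch(ch,
      carry = NULL,
      fixed = sprintf("%s{%s}", info$name, sample(info$labels, 1)),
      succ = sprintf("succ(%s)", info$name),
      pred = sprintf("pred(%s)", info$name))
    if (!is.null(pat)) product_pats <- c(product_pats, pat)
  }
  reactant <- sprintf("A(%s)", paste(reactant_pats, collapse = ", "))
  product <- if (length(product_pats)) {
    sprintf("A(%s)", paste(product_pats, collapse = ", "))
  } else "A"
  rx <- sprintf("r1 : %s%s -> %s%s | MA : k", reactant,
                if (with_catalyst) " + C" else "", product,
                if (with_catalyst) " + C" else "")
  lines <- c("[globals]", "k = 1",
             "[species]", sprintf("A(%s) = 1", paste(site_defs, collapse = ", ")),
             if (with_catalyst) "C = 1",
             "[reactions]", rx)
  build_model(parse_model(lines), policy = "off")$model
}
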