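# Two-clade coding-sequence evolver with a planted-truth event log.
#
# The evolver works entirely in ancestral coordinates: substitutions and
# deletions target ancestral sites, insertions anchor after an ancestral
# site and never receive later events. The emitted alignment is therefore a
# pure function of (ancestor, event log) — see replay_events() — which is
# what makes every downstream scanner testable against exact truth.

#' Simulation configuration for the two-clade panel
#'
#' Defaults emulate the data the pipeline is designed for: two clades of 3
#' and 4 strains whose within-clade identity greatly exceeds the
#' between-clade identity, CDS lengths of a few hundred to a few thousand
#' nt at AT-rich composition, transition-dominated substitutions, and
#' INDELs dominated by multiple-of-three lengths.
#'
#' @param n_genes Number of ortholog genes in the panel.
#' @param len_range CDS length range in nt (multiples of 3 sampled
#'   uniformly).
#' @param gc Target GC fraction of the ancestral CDSs.
#' @param clade_sizes Integer pair: strains in clade A and clade B.
#' @param sub_rate Substitutions per site on each tip branch.
#' @param kappa Transition/transversion rate ratio; the probability that a
#'   substitution is a transition is `kappa / (kappa + 2)`.
#' @param indel_rate INDEL events per site on each tip branch.
#' @param indel_geom_p Geometric parameter for small INDEL lengths.
#' @param frame_mass Probability that an INDEL length is a multiple of
#'   three (frame-preserving).
#' @param large_prob Probability that an INDEL is large (> 40 bp).
#' @param large_range Length range for large INDELs.
#' @param stem_mult Rate multiplier on the two clade stem branches; values
#'   well above 1 create the within-clade >> between-clade identity
#'   structure.
#' @param seed Integer seed used by [simulate_panel()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 40L,
                       len_range = c(300L, 3300L),
                       gc = 0.34,
                       clade_sizes = c(3L, 4L),
                       sub_rate = 0.005,
                       kappa = 2,
                       indel_rate = 2.5e-4,
                       indel_geom_p = 0.35,
                       frame_mass = 0.85,
                       large_prob = 0.05,
                       large_range = c(41L, 120L),
                       stem_mult = 10,
                       seed = 42L) {
  cfg <- list(n_genes = as.integer(n_genes), len_range = as.integer(len_range),
              gc = gc, clade_sizes = as.integer(clade_sizes),
              sub_rate = sub_rate, kappa = kappa, indel_rate = indel_rate,
              indel_geom_p = indel_geom_p, frame_mass = frame_mass,
              large_prob = large_prob, large_range = as.integer(large_range),
              stem_mult = stem_mult, seed = as.integer(seed))
  probs <- c(frame_mass = frame_mass, large_prob = large_prob,
             indel_geom_p = indel_geom_p, gc = gc)
  if (any(probs < 0 | probs > 1)) stop("sim_config: probabilities must be in [0,1]")
  if (sub_rate < 0 || indel_rate < 0 || kappa < 0 || stem_mult < 0) {
    stop("sim_config: rates must be non-negative")
  }
  if (any(cfg$clade_sizes < 1L)) stop("sim_config: clade sizes must be >= 1")
  if (cfg$len_range[1] < 9L || cfg$len_range[2] < cfg$len_range[1]) {
    stop("sim_config: invalid length range")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Strain table implied by a configuration: A1..Am in clade A, B1..Bn in B.
sim_strain_table <- function(cfg) {
  a <- paste0("A", seq_len(cfg$clade_sizes[1]))
  b <- paste0("B", seq_len(cfg$clade_sizes[2]))
  strain_table(c(a, b), c(rep("A", length(a)), rep("B", length(b))))
}

#' Generate ancestral coding sequences
#'
#' Each gene starts with ATG, ends with a stop codon and contains no
#' internal stop; internal codon bases are drawn i.i.d. at the target GC
#' with stop codons rejected and redrawn. Draws from R's global RNG stream
#' (seed via [simulate_panel()] or `set.seed()`).
#'
#' @param cfg A [sim_config()].
#' @return Named character vector of CDS sequences (`g001`, `g002`, ...).
#' @export
generate_ancestor <- function(cfg) {
  base_p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2,
              G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
  lens <- sample(seq(cfg$len_range[1], cfg$len_range[2], by = 3L),
                 cfg$n_genes, replace = TRUE)
  out <- character(cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    k_int <- lens[g] %/% 3L - 2L
    cods <- character(k_int)
    todo <- seq_len(k_int)
    for (round in 1:100) {
      draw <- sample(DNA_BASES, 3L * length(todo), replace = TRUE, prob = base_p)
      cand <- apply(matrix(draw, nrow = 3L), 2L, paste, collapse = "")
      cods[todo] <- cand
      todo <- which(cods %in% STOP_CODONS)
      if (length(todo) == 0L) break
    }
    if (length(todo) > 0L) stop("generation error: could not avoid stop codons")
    out[g] <- paste0("ATG", paste(cods, collapse = ""), sample(STOP_CODONS, 1L))
  }
  names(out) <- sprintf("g%03d", seq_len(cfg$n_genes))
  out
}

# Truncated geometric-style length draw satisfying a predicate.
draw_len <- function(ok, draw1, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    x <- draw1()
    if (ok(x)) return(x)
  }
  stop("generation error: could not draw an admissible INDEL length")
}

draw_indel_length <- function(cfg) {
  frame <- stats::runif(1) < cfg$frame_mass
  large <- stats::runif(1) < cfg$large_prob
  if (large) {
    cand <- seq(cfg$large_range[1], cfg$large_range[2])
    cand <- if (frame) cand[cand %% 3L == 0L] else cand[cand %% 3L != 0L]
    sample(cand, 1L)
  } else if (frame) {
    draw_len(function(x) x <= 40L,
             function() 3L * (1L + stats::rgeom(1L, cfg$indel_geom_p)))
  } else {
    draw_len(function(x) x <= 40L && x %% 3L != 0L,
             function() 1L + stats::rgeom(1L, cfg$indel_geom_p))
  }
}

# Transition partner of each base.
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

# Evolve one branch: mutate `state` (bases at ancestral coords) and `alive`
# (not yet deleted on this path), returning new state plus drawn events.
evolve_branch <- function(state, alive, cfg, mult, carriers, gene_id,
                          next_id) {
  L <- length(state)
  elig <- rep(FALSE, L)
  if (L >= 7L) elig[4:(L - 3L)] <- TRUE   # keep start/stop codons intact
  events <- list()
  elig_alive <- which(alive & elig)

  n_sub <- stats::rbinom(1L, length(elig_alive), min(1, cfg$sub_rate * mult))
  if (n_sub > 0L) {
    pos <- sample(elig_alive, n_sub)
    is_ts <- stats::runif(n_sub) < cfg$kappa / (cfg$kappa + 2)
    for (i in seq_len(n_sub)) {
      from <- state[pos[i]]
      to <- if (is_ts[i]) TS_PARTNER[[from]] else sample(TV_PARTNERS[[from]], 1L)
      events[[length(events) + 1L]] <- list(
        event_id = next_id(), gene_id = gene_id, type = "substitution",
        anc_pos = pos[i], length = 1L, from = from, to = to, seq = "",
        carriers = carriers)
      state[pos[i]] <- to
    }
  }

  n_ind <- stats::rbinom(1L, length(elig_alive), min(1, cfg$indel_rate * mult))
  for (i in seq_len(n_ind)) {
    len <- draw_indel_length(cfg)
    if (stats::runif(1) < 0.5) {                       # deletion
      ok <- alive & elig
      cs <- c(0L, cumsum(ok))
      starts <- seq_len(L - len + 1L)
      valid <- starts[cs[starts + len] - cs[starts] == len]
      if (length(valid) == 0L) next                    # no room; skip event
      s <- if (length(valid) == 1L) valid else sample(valid, 1L)
      events[[length(events) + 1L]] <- list(
        event_id = next_id(), gene_id = gene_id, type = "deletion",
        anc_pos = s, length = len, from = "", to = "",
        seq = paste(state[s:(s + len - 1L)], collapse = ""),
        carriers = carriers)
      alive[s:(s + len - 1L)] <- FALSE
    } else {                                           # insertion
      if (length(which(alive & elig)) == 0L) next
      anchor <- sample(which(alive & elig), 1L)
      donor <- which(alive[seq_len(anchor)])
      donor <- utils::tail(donor, len)
      seq_chars <- state[donor]
      if (length(seq_chars) < len) {
        seq_chars <- c(sample(state[alive], len - length(seq_chars),
                              replace = TRUE), seq_chars)
      }
      events[[length(events) + 1L]] <- list(
        event_id = next_id(), gene_id = gene_id, type = "insertion",
        anc_pos = anchor, length = len, from = "", to = "",
        seq = paste(seq_chars, collapse = ""), carriers = carriers)
    }
  }
  list(state = state, alive = alive, events = events)
}

events_to_df <- function(events) {
  if (length(events) == 0L) {
    return(data.frame(event_id = integer(0), gene_id = character(0),
                      type = character(0), branch = character(0),
                      anc_pos = integer(0), length = integer(0),
                      from = character(0), to = character(0),
                      seq = character(0), carriers = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    event_id = vapply(events, `[[`, 0L, "event_id"),
    gene_id = vapply(events, `[[`, "", "gene_id"),
    type = vapply(events, `[[`, "", "type"),
    branch = vapply(events, `[[`, "", "branch"),
    anc_pos = vapply(events, `[[`, 0L, "anc_pos"),
    length = vapply(events, `[[`, 0L, "length"),
    from = vapply(events, `[[`, "", "from"),
    to = vapply(events, `[[`, "", "to"),
    seq = vapply(events, `[[`, "", "seq"),
    carriers = vapply(events, function(e) join_strains(e$carriers), ""),
    stringsAsFactors = FALSE)
}

# Reconstruct one gene's alignment (plus the gapped ancestor row) purely
# from the ancestor sequence and the event table.
emit_gene_alignment <- function(gene_id, anc_seq, ev, tip_paths) {
  anc <- strsplit(anc_seq, "", fixed = TRUE)[[1]]
  L <- length(anc)
  tips <- names(tip_paths)

  ins <- ev[ev$type == "insertion", , drop = FALSE]
  ins <- ins[order(ins$anc_pos, ins$event_id), , drop = FALSE]
  add <- integer(L)
  if (nrow(ins) > 0L) {
    for (i in seq_len(nrow(ins))) add[ins$anc_pos[i]] <- add[ins$anc_pos[i]] + ins$length[i]
  }
  final_of_anc <- seq_len(L) + c(0L, cumsum(add)[-L])
  total <- L + sum(add)

  # Start column of each insertion block in the final layout.
  ins_start <- integer(nrow(ins))
  if (nrow(ins) > 0L) {
    off <- integer(L)
    for (i in seq_len(nrow(ins))) {
      a <- ins$anc_pos[i]
      ins_start[i] <- final_of_anc[a] + 1L + off[a]
      off[a] <- off[a] + ins$length[i]
    }
  }

  carrier_list <- split_strains(ev$carriers)
  rows <- character(length(tips) + 1L)
  names(rows) <- c(tips, ".ancestor")
  for (tip in tips) {
    on_path <- vapply(carrier_list, function(cs) tip %in% cs, TRUE)
    state <- anc
    evt <- ev[on_path & ev$type == "substitution", , drop = FALSE]
    evt <- evt[order(evt$event_id), , drop = FALSE]
    if (nrow(evt) > 0L) state[evt$anc_pos] <- evt$to
    del <- ev[on_path & ev$type == "deletion", , drop = FALSE]
    if (nrow(del) > 0L) {
      for (i in seq_len(nrow(del))) {
        state[del$anc_pos[i]:(del$anc_pos[i] + del$length[i] - 1L)] <- "-"
      }
    }
    row <- rep("-", total)
    row[final_of_anc] <- state
    if (nrow(ins) > 0L) {
      ins_on <- which(vapply(split_strains(ins$carriers),
                             function(cs) tip %in% cs, TRUE))
      for (i in ins_on) {
        row[ins_start[i]:(ins_start[i] + ins$length[i] - 1L)] <-
          strsplit(ins$seq[i], "", fixed = TRUE)[[1]]
      }
    }
    rows[tip] <- paste(row, collapse = "")
  }
  rowa <- rep("-", total)
  rowa[final_of_anc] <- anc
  rows[".ancestor"] <- paste(rowa, collapse = "")

  # Final-coordinate start column per event.
  column <- integer(nrow(ev))
  column[ev$type != "insertion"] <- final_of_anc[ev$anc_pos[ev$type != "insertion"]]
  if (nrow(ins) > 0L) column[match(ins$event_id, ev$event_id)] <- ins_start
  list(rows = rows, column = column)
}

#' Rebuild panel alignments from the ancestor and the event log
#'
#' The emitted panel is a deterministic function of the recorded events;
#' this is the event-sourcing guarantee the truth channel rests on.
#'
#' @param ancestors Named character vector of ancestral CDSs.
#' @param events Event table as found in `panel$truth$events`.
#' @param strains A [strain_table()].
#' @return Named list of [gene_alignment()]s including a `.ancestor` row in
#'   an attribute `ancestor_aln`.
#' @export
replay_events <- function(ancestors, events, strains) {
  tip_paths <- stats::setNames(as.list(strains$strain_id), strains$strain_id)
  alns <- vector("list", length(ancestors))
  names(alns) <- names(ancestors)
  anc_rows <- character(length(ancestors))
  names(anc_rows) <- names(ancestors)
  for (g in names(ancestors)) {
    ev <- events[events$gene_id == g, , drop = FALSE]
    em <- emit_gene_alignment(g, ancestors[[g]], ev, tip_paths)
    rows <- em$rows
    anc_rows[g] <- rows[".ancestor"]
    alns[[g]] <- gene_alignment(g, rows[setdiff(names(rows), ".ancestor")])
  }
  attr(alns, "ancestor_aln") <- anc_rows
  alns
}

#' Evolve a panel of genes down the two-clade topology
#'
#' Topology `((A1,A2,A3),(B1,...,Bn))` with per-branch K80-style
#' substitutions (transition probability `kappa/(kappa+2)` among the three
#' alternatives) and INDELs per the configured length law. Events on a stem
#' branch carry every strain of that clade. The true alignment is emitted
#' from the event history; no realignment is performed.
#'
#' @param ancestors Named character vector from [generate_ancestor()].
#' @param cfg A [sim_config()].
#' @return List with `alignments` (per-gene [gene_alignment()]), `strains`,
#'   and `truth` (`events` data frame with final 1-based `column`
#'   coordinates and an `interferes` flag, plus per-gene aligned ancestor
#'   rows in `ancestor_aln`).
#' @export
evolve_panel <- function(ancestors, cfg) {
  strains <- sim_strain_table(cfg)
  tipsA <- lineage_strains(strains, "A")
  tipsB <- lineage_strains(strains, "B")
  counter <- local({i <- 0L; function() {i <<- i + 1L; i}})

  all_events <- list()
  for (g in names(ancestors)) {
    anc <- strsplit(ancestors[[g]], "", fixed = TRUE)[[1]]
    root <- list(state = anc, alive = rep(TRUE, length(anc)))
    branches <- c(
      list(list(name = "stem_A", from = "root", carriers = tipsA, mult = cfg$stem_mult),
           list(name = "stem_B", from = "root", carriers = tipsB, mult = cfg$stem_mult)),
      lapply(tipsA, function(t) list(name = t, from = "stem_A", carriers = t, mult = 1)),
      lapply(tipsB, function(t) list(name = t, from = "stem_B", carriers = t, mult = 1)))
    node_state <- list(root = root)
    for (br in branches) {
      parent <- node_state[[br$from]]
      res <- evolve_branch(parent$state, parent$alive, cfg, br$mult,
                           br$carriers, g, counter)
      node_state[[br$name]] <- list(state = res$state, alive = res$alive)
      res$events <- lapply(res$events, function(e) {e$branch <- br$name; e})
      all_events <- c(all_events, res$events)
    }
  }
  events <- events_to_df(all_events)
  alns <- replay_events(ancestors, events, strains)
  anc_rows <- attr(alns, "ancestor_aln")
  attr(alns, "ancestor_aln") <- NULL

  # Final coordinates per event (recomputed per gene by the emitter).
  events$column <- rep(NA_integer_, nrow(events))
  tip_paths <- stats::setNames(as.list(strains$strain_id), strains$strain_id)
  for (g in names(ancestors)) {
    idx <- which(events$gene_id == g)
    if (length(idx) == 0L) next
    em <- emit_gene_alignment(g, ancestors[[g]], events[idx, , drop = FALSE],
                              tip_paths)
    events$column[idx] <- em$column
  }
  events <- flag_interference(events)

  list(alignments = alns, strains = strains,
       truth = list(events = events,
                    aversions = data.frame(gene_id = character(0),
                                           codon = character(0),
                                           target = character(0),
                                           strains = character(0),
                                           stringsAsFactors = FALSE),
                    ancestor_aln = anc_rows))
}

carriers_intersect <- function(a, b) length(intersect(a, b)) > 0L

# Flag planted events whose footprints can interact in the emitted
# alignment, so that scanner-vs-truth comparisons can restrict themselves
# to cleanly recoverable events. The rules are conservative where the
# emitted gap structure would merge, split or shadow runs:
#   sub-sub  same ancestral site                      -> both flagged
#   sub-del  site inside span, shared carriers        -> both flagged
#   del-del  spans (pad 1) overlap and carriers meet,
#            or identical span in disjoint carriers   -> both flagged
#   ins-del  anchor strictly inside the deletion span -> both flagged
#   ins-ins  same anchor                              -> both flagged
flag_interference <- function(events) {
  events$interferes <- rep(FALSE, nrow(events))
  if (nrow(events) == 0L) return(events)
  cl <- split_strains(events$carriers)
  for (g in unique(events$gene_id)) {
    idx <- which(events$gene_id == g)
    ev <- events[idx, , drop = FALSE]
    flag <- logical(nrow(ev))
    subs <- which(ev$type == "substitution")
    dels <- which(ev$type == "deletion")
    inss <- which(ev$type == "insertion")

    if (length(subs) > 1L) {
      dup_pos <- ev$anc_pos[subs][duplicated(ev$anc_pos[subs])]
      flag[subs[ev$anc_pos[subs] %in% dup_pos]] <- TRUE
    }
    for (d in dels) {
      s <- ev$anc_pos[d]; e <- s + ev$length[d] - 1L
      if (length(subs) > 0L) {
        hit <- subs[ev$anc_pos[subs] >= s & ev$anc_pos[subs] <= e]
        hit <- hit[vapply(hit, function(h)
          carriers_intersect(cl[[idx[h]]], cl[[idx[d]]]), TRUE)]
        if (length(hit) > 0L) {flag[hit] <- TRUE; flag[d] <- TRUE}
      }
      for (d2 in dels[dels > d]) {
        s2 <- ev$anc_pos[d2]; e2 <- s2 + ev$length[d2] - 1L
        overlap <- (s2 <= e + 1L) && (e2 >= s - 1L)
        same <- (s2 == s) && (ev$length[d2] == ev$length[d])
        if (overlap && (same ||
                        carriers_intersect(cl[[idx[d]]], cl[[idx[d2]]]))) {
          flag[d] <- TRUE; flag[d2] <- TRUE
        }
      }
      if (length(inss) > 0L) {
        hit <- inss[ev$anc_pos[inss] >= s & ev$anc_pos[inss] < e]
        if (length(hit) > 0L) {flag[hit] <- TRUE; flag[d] <- TRUE}
      }
    }
    if (length(inss) > 1L) {
      dup_anchor <- ev$anc_pos[inss][duplicated(ev$anc_pos[inss])]
      flag[inss[ev$anc_pos[inss] %in% dup_anchor]] <- TRUE
    }
    events$interferes[idx] <- flag
  }
  events
}

#' Plant a codon-aversion difference into a panel
#'
#' Synonymously recodes every occurrence of `codon` in the target strains'
#' copies of one gene (the protein is unchanged) and logs the aversion in
#' the truth channel, so that downstream motif extraction has a known
#' positive.
#'
#' @param panel Panel from [simulate_panel()] / [evolve_panel()].
#' @param gene_id Gene to recode.
#' @param codon Sense codon with at least one synonym; recoding a
#'   single-codon family (ATG, TGG) or a stop codon is an infeasibility
#'   error.
#' @param target A lineage label or a vector of strain ids.
#' @return The modified panel.
#' @export
plant_cam_difference <- function(panel, gene_id, codon, target) {
  if (!(codon %in% SENSE_CODONS)) {
    stop("infeasibility error: '", codon, "' is not a sense codon")
  }
  fam <- SYN_FAMILIES[[CODON_AA[[codon]]]]
  if (length(fam) < 2L) {
    stop("infeasibility error: '", codon, "' has no synonym to recode into")
  }
  aln <- panel$alignments[[gene_id]]
  if (is.null(aln)) stop("unknown gene '", gene_id, "'")
  targets <- if (all(target %in% panel$strains$lineage)) {
    lineage_strains(panel$strains, target)
  } else {
    if (!all(target %in% panel$strains$strain_id)) {
      stop("unknown target '", paste(target, collapse = ","), "'")
    }
    target
  }
  alts <- setdiff(fam, codon)
  for (s in targets) {
    chars <- strsplit(aln$seqs[[s]], "", fixed = TRUE)[[1]]
    idx <- which(chars != "-")
    k <- length(idx) %/% 3L
    for (j in seq_len(k)) {
      pos <- idx[(3L * j - 2L):(3L * j)]
      if (paste(chars[pos], collapse = "") == codon) {
        repl <- if (length(alts) == 1L) alts else sample(alts, 1L)
        chars[pos] <- strsplit(repl, "", fixed = TRUE)[[1]]
      }
    }
    aln$seqs[[s]] <- paste(chars, collapse = "")
  }
  panel$alignments[[gene_id]] <- aln
  panel$truth$aversions <- rbind(
    panel$truth$aversions,
    data.frame(gene_id = gene_id, codon = codon,
               target = paste(target, collapse = ","),
               strains = join_strains(targets), stringsAsFactors = FALSE))
  panel
}

#' Simulate a full two-clade ortholog panel
#'
#' Seeds the RNG from `cfg$seed`, generates the ancestor, evolves it down
#' the two-clade topology and optionally plants codon-aversion differences.
#'
#' @param cfg A [sim_config()].
#' @param plants Optional list of `list(gene_id=, codon=, target=)` entries
#'   passed to [plant_cam_difference()].
#' @return Panel list: `config`, `strains`, `ancestors`, `alignments`,
#'   `truth`.
#' @export
simulate_panel <- function(cfg = sim_config(), plants = NULL) {
  set.seed(cfg$seed)
  ancestors <- generate_ancestor(cfg)
  panel <- evolve_panel(ancestors, cfg)
  panel$ancestors <- ancestors
  panel$config <- cfg
  for (p in plants) {
    panel <- plant_cam_difference(panel, p$gene_id, p$codon, p$target)
  }
  panel
}

#' Write a simulated panel to disk
#'
#' Per-gene aligned FASTA under `dir/alignments/`, the strain table as TSV,
#' and the truth channel (events keyed by gene, aversions, aligned ancestor
#' rows) as JSON.
#'
#' @param panel Panel from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE, showWarnings = FALSE)
  for (g in names(panel$alignments)) {
    write_alignment(panel$alignments[[g]],
                    file.path(dir, "alignments", paste0(g, ".fasta")))
  }
  write_strain_table(panel$strains, file.path(dir, "strains.tsv"))
  truth <- list(
    events = split(panel$truth$events, panel$truth$events$gene_id),
    aversions = panel$truth$aversions,
    ancestor_aln = as.list(panel$truth$ancestor_aln))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
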