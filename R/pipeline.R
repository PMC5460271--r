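#' Default run configuration
#'
#' Returns the full configuration list with every analysis parameter at
#' its conventional default (SASA exposure 0.20; contact cutoffs 4.0
#' Angstrom for interface pairs, 3.9 for ligand contacts, 4.5 for
#' persistent contacts; persistence fraction 0.75; z-score cutoffs 1.5 for
#' betweenness and 1.0 for delta path length; DCA pseudocount 0.5,
#' identity threshold 0.8, DI threshold 0.8). A minimal user config names
#' only the inputs; everything else is merged from here.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    inputs = list(structure = NULL, monomer_chain = NULL, partner_chain = NULL,
                  ligand_names = NULL, trajectory = NULL,
                  msa_single = NULL, msa_double = NULL),
    sasa = list(probe = 1.4, n_points = 960L, exposed_threshold = 0.20),
    contacts = list(interface_cutoff = 4.0, ligand_cutoff = 3.9),
    network = list(contact_cutoff = 4.5, persistence = 0.75,
                   frame_start = 1L),
    metrics = list(betweenness_z_cutoff = 1.5, dpl_z_cutoff = 1.0),
    dca = list(lambda = 0.5, identity_threshold = 0.8, di_threshold = 0.8,
               max_gap_fraction = 0.5, min_separation = 2L, columns = NULL),
    hp = list(pos_pair = NULL, n_single = 31L, n_double = 11L, reps = 5L),
    seed = 1L,
    output_dir = "results"
  )
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a run configuration
#'
#' Checks that every threshold lies in its valid range and that referenced
#' input files exist. Called by [run_pipeline()]; exported so drivers can
#' fail fast.
#'
#' @param cfg Configuration list (possibly partial; merged over
#'   [default_config()]).
#' @return The merged, validated configuration, invisibly on success;
#'   stops with a message naming the offending field otherwise.
#' @export
validate_config <- function(cfg) {
  cfg <- .merge_config(default_config(), cfg)
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
  chk(cfg$sasa$probe > 0, "sasa.probe must be > 0")
  chk(cfg$sasa$exposed_threshold >= 0 && cfg$sasa$exposed_threshold < 1,
      "sasa.exposed_threshold must be in [0, 1)")
  chk(cfg$contacts$interface_cutoff > 0, "contacts.interface_cutoff must be > 0")
  chk(cfg$network$persistence > 0 && cfg$network$persistence <= 1,
      "network.persistence must be in (0, 1]")
  chk(cfg$dca$lambda >= 0, "dca.lambda must be >= 0")
  chk(cfg$dca$identity_threshold > 0 && cfg$dca$identity_threshold <= 1,
      "dca.identity_threshold must be in (0, 1]")
  chk(cfg$dca$max_gap_fraction >= 0 && cfg$dca$max_gap_fraction <= 1,
      "dca.max_gap_fraction must be in [0, 1]")
  for (f in c("structure", "trajectory", "msa_single", "msa_double")) {
    p <- cfg$inputs[[f]]
    if (!is.null(p)) chk(file.exists(p), paste0("inputs.", f, " not found: ", p))
  }
  invisible(cfg)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes whichever stages the inputs enable, in dependency order:
#' structure -> SASA classification and interface/ligand contacts;
#' trajectory -> motion correlation -> dynamical network -> graph metrics;
#' alignments -> conservation, DCA direct information, and (when both
#' domain classes and a position pair are given) the hydrophobic-polar
#' pattern resampling. All tables are written under `cfg$output_dir`
#' together with a JSON run manifest carrying the parameters, seed and a
#' config hash; reruns with an identical config are byte-identical.
#'
#' @param cfg Configuration list (see [default_config()]), or path to a
#'   YAML file.
#' @param skip_existing Skip a stage when all its output files already
#'   exist (default `FALSE`).
#' @return Invisible list of stage results (`classification`, `pairs`,
#'   `ligand`, `metrics`, `dca_single`, `dca_double`, `conservation`,
#'   `hp`, `manifest`).
#' @export
run_pipeline <- function(cfg, skip_existing = FALSE) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  cfg <- validate_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  outfile <- function(nm) file.path(cfg$output_dir, nm)
  stage <- function(name, files, fun) {
    if (skip_existing && all(file.exists(outfile(files)))) {
      message("[", name, "] outputs exist, skipped")
      return(NULL)
    }
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(cfg$inputs$structure)) {
    out$classification <- stage("classify", "classification.tsv", function() {
      s <- read_structure(cfg$inputs$structure)
      cm <- cfg$inputs$monomer_chain
      monomer <- extract_chains(s, cm, keep_het = FALSE)
      lig <- NULL
      if (!is.null(cfg$inputs$ligand_names)) {
        lig <- find_ligand_contacts(s, cfg$inputs$ligand_names,
                                    cfg$contacts$ligand_cutoff)
      }
      sm <- compute_sasa(monomer, cfg$sasa$probe, cfg$sasa$n_points)
      sc <- compute_sasa(s, cfg$sasa$probe, cfg$sasa$n_points,
                         include_het = TRUE)
      sc <- sc[sc$chain == cm, , drop = FALSE]
      cls <- classify_residues(sm, sc, cfg$sasa$exposed_threshold, lig)
      write_classification(cls, outfile("classification.tsv"))
      cls
    })
    if (!is.null(cfg$inputs$partner_chain)) {
      out$pairs <- stage("contacts", "contact_pairs.tsv", function() {
        s <- read_structure(cfg$inputs$structure)
        pr <- find_interface_pairs(s, cfg$inputs$monomer_chain,
                                   cfg$inputs$partner_chain,
                                   cfg$contacts$interface_cutoff)
        write_contact_pairs(pr, outfile("contact_pairs.tsv"))
        pr
      })
    }
  }

  if (!is.null(cfg$inputs$trajectory)) {
    out$metrics <- stage("network", c("metrics.tsv", "network.graphml"),
                         function() {
      traj <- read_trajectory(cfg$inputs$trajectory,
                              frame_start = cfg$network$frame_start)
      corr <- motion_correlation(traj)
      pers <- contact_persistence(traj, cfg$network$contact_cutoff,
                                  cfg$network$persistence)
      g <- build_network(corr, pers)
      write_network(g, graphml = outfile("network.graphml"),
                    json = outfile("network.json"))
      write_correlation(corr, outfile("correlation.tsv"))
      m <- network_metrics(g, cfg$metrics$betweenness_z_cutoff,
                           cfg$metrics$dpl_z_cutoff)
      write_metrics(m, outfile("metrics.tsv"), outfile("network_summary.json"))
      m
    })
  }

  for (dom in c("single", "double")) {
    path <- cfg$inputs[[paste0("msa_", dom)]]
    if (is.null(path)) next
    out[[paste0("dca_", dom)]] <- stage(paste0("dca_", dom),
                                        paste0("di_", dom, ".tsv"), function() {
      res <- run_dca(path, lambda = cfg$dca$lambda,
                     identity_threshold = cfg$dca$identity_threshold,
                     di_threshold = cfg$dca$di_threshold,
                     max_gap_fraction = cfg$dca$max_gap_fraction,
                     min_separation = cfg$dca$min_separation,
                     columns = cfg$dca$columns)
      write_dca(res, outfile(paste0("di_", dom, ".tsv")),
                outfile(paste0("dca_", dom, "_manifest.json")))
      res
    })
  }

  if (!is.null(cfg$inputs$msa_single)) {
    out$conservation <- stage("conservation", "conservation.tsv", function() {
      cons <- conservation_grades(read_alignment(cfg$inputs$msa_single))
      write_tsv(cons, outfile("conservation.tsv"))
      cons
    })
  }

  if (!is.null(cfg$inputs$msa_single) && !is.null(cfg$inputs$msa_double) &&
      !is.null(cfg$hp$pos_pair)) {
    out$hp <- stage("hp", "hp_patterns.tsv", function() {
      hp <- hp_pattern_analysis(read_alignment(cfg$inputs$msa_single),
                                read_alignment(cfg$inputs$msa_double),
                                pos_pair = cfg$hp$pos_pair,
                                n_single = cfg$hp$n_single,
                                n_double = cfg$hp$n_double,
                                reps = cfg$hp$reps, seed = cfg$seed)
      write_tsv(hp, outfile("hp_patterns.tsv"))
      hp
    })
  }

  cfg_for_hash <- cfg
  tf <- tempfile(); saveRDS(cfg_for_hash, tf, version = 2)
  manifest <- list(package = "lectinet",
                   version = as.character(utils::packageVersion("lectinet")),
                   config = cfg, config_hash = unname(tools::md5sum(tf)),
                   seed = cfg$seed,
                   stages = names(out))
  unlink(tf)
  jsonlite::write_json(manifest, outfile("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out$manifest <- manifest
  invisible(out)
}

#' Write a human-readable summary report
#'
#' Summarises whatever stage results are present: classification counts,
#' interface contact pairs, flagged high-betweenness and high-DPL
#' residues with their z-scores, closeness tiers, DI-flagged pairs and
#' hydrophobic-polar pattern fractions.
#'
#' @param results Stage-result list from [run_pipeline()] (any subset of
#'   its elements).
#' @param path Output text file; `NULL` returns the lines invisibly.
#' @return Character vector of report lines, invisibly.
#' @export
write_report <- function(results, path = NULL) {
  if (!length(results)) stop("no stage results to report")
  ln <- c("lectinet analysis report",
          "========================", "")
  if (!is.null(results$classification)) {
    cls <- results$classification
    tab <- table(cls$category)
    ln <- c(ln, "Residue classification:",
            sprintf("  %-15s %d", names(tab), as.integer(tab)),
            sprintf("  ligand-binding flag set on %d residue(s)",
                    sum(cls$ligand_binding)), "")
  }
  if (!is.null(results$pairs)) {
    pr <- results$pairs
    ln <- c(ln, sprintf("Interface contact pairs (< cutoff): %d", nrow(pr)),
            sprintf("  %s:%s%d - %s:%s%d  %.2f A", pr$chain_a, pr$resid_a,
                    pr$resno_a, pr$chain_b, pr$resid_b, pr$resno_b,
                    pr$distance), "")
  }
  if (!is.null(results$metrics)) {
    nd <- results$metrics$nodes
    ln <- c(ln, sprintf("Dynamical network: %d nodes, %d edges, CPL = %.4f",
                        results$metrics$summary$n_nodes,
                        results$metrics$summary$n_edges,
                        results$metrics$summary$cpl),
            "  High-betweenness residues (z > cutoff):")
    fb <- nd[nd$flag_betweenness, , drop = FALSE]
    fb <- fb[order(-fb$z_betweenness), , drop = FALSE]
    ln <- c(ln, if (nrow(fb)) sprintf("    %s  z = %.2f", fb$node,
                                      fb$z_betweenness) else "    (none)")
    fd <- nd[nd$flag_dpl, , drop = FALSE]
    fd <- fd[order(-fd$z_dpl), , drop = FALSE]
    ln <- c(ln, "  High-DPL residues (z > cutoff):",
            if (nrow(fd)) sprintf("    %s  z = %.2f", fd$node, fd$z_dpl)
            else "    (none)",
            sprintf("  Closeness tiers: %s",
                    paste(sprintf("%s=%d", names(table(nd$tier)),
                                  as.integer(table(nd$tier))), collapse = ", ")),
            "")
  }
  for (dom in c("single", "double")) {
    res <- results[[paste0("dca_", dom)]]
    if (is.null(res)) next
    fl <- res$pairs[res$pairs$flagged, , drop = FALSE]
    ln <- c(ln, sprintf("DCA (%s-domain): M = %d, L = %d, M_eff = %.1f", dom,
                        res$manifest$M, res$manifest$L, res$manifest$M_eff),
            sprintf("  DI-flagged pairs (DI > %.2f): %d",
                    res$manifest$di_threshold, nrow(fl)),
            if (nrow(fl)) sprintf("    %d-%d  DI = %.3f", fl$pos_i, fl$pos_j,
                                  fl$DI),
            "")
  }
  if (!is.null(results$hp)) {
    hp <- results$hp
    for (d in unique(hp$domain)) {
      sub <- hp[hp$domain == d, , drop = FALSE]
      ln <- c(ln, sprintf(
        "HP patterns (%s-domain, %d reps): PP %.2f, PH %.2f, HH %.2f", d,
        nrow(sub), mean(sub$frac_polar_polar),
        mean(sub$frac_polar_hydrophobic),
        mean(sub$frac_hydrophobic_hydrophobic)))
    }
    ln <- c(ln, "")
  }
  if (!is.null(path)) writeLines(ln, path)
  invisible(ln)
}
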