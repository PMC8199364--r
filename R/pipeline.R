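# Config-driven orchestration: run the full analysis battery over one input
# trajectory or a set of synthetic noise tiers, writing machine-readable
# CSV tables and a JSON manifest.  All randomness flows through the config
# seed, so a fixed config + seed gives byte-identical outputs.

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  config
}

config_criterion <- function(config) {
  hc <- config$hbond_criterion
  hbond_criterion(
    max_da_distance = if (is.null(hc$distance)) 0.35 else hc$distance,
    max_hda_angle = if (is.null(hc$angle)) 30 else hc$angle)
}

config_blocking <- function(config) {
  bl <- config$blocking
  list(n_blocks = if (is.null(bl$n_blocks)) 5L else as.integer(bl$n_blocks),
       window = bl$window)
}

# Build the tiered trajectory set described by a synthetic config block.
synthetic_tiers <- function(syn, seed) {
  kind <- if (is.null(syn$kind)) "wtrop_like" else syn$kind
  bundle <- build_bundle(kind,
                         chain_length = syn$chain_length,
                         loop_length = if (is.null(syn$loop_length)) 9L else syn$loop_length,
                         separation = if (is.null(syn$separation)) 1.0 else syn$separation)
  n_frames <- if (is.null(syn$n_frames)) 200L else as.integer(syn$n_frames)
  dt <- if (is.null(syn$dt)) 0.1 else syn$dt
  sig <- syn$sigma
  base_sigma <- sigma_profile(bundle$annotation,
                              helix = if (is.null(sig$helix)) 0.01 else sig$helix,
                              loop = if (is.null(sig$loop)) 0.03 else sig$loop,
                              tail = if (is.null(sig$tail)) 0.05 else sig$tail)
  tiers <- syn$tiers
  if (is.null(tiers)) tiers <- list(T300 = 1, T350 = 2, T368 = 3)
  trajs <- list()
  sigmas <- list()
  for (i in seq_along(tiers)) {
    label <- names(tiers)[i]
    scale <- as.numeric(tiers[[i]])
    sigmas[[label]] <- base_sigma * scale
    trajs[[label]] <- generate_trajectory(
      bundle$system, n_frames,
      noise_model(base_sigma * scale, seed = seed + i), dt = dt)
  }
  list(kind = kind, bundle = bundle, trajectories = trajs, sigmas = sigmas,
       n_frames = n_frames, dt = dt)
}

load_input <- function(inp) {
  traj <- read_trajectory(inp$trajectory, dt = inp$dt)
  annotation <- if (!is.null(inp$annotation)) read_annotation(inp$annotation) else NULL
  list(kind = if (is.null(inp$kind)) "input" else inp$kind,
       bundle = list(system = traj$topology, annotation = annotation),
       trajectories = setNames(list(traj),
                               if (is.null(inp$label)) "input" else inp$label))
}

write_stage_csv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages (`rmsd`, `rmsf`, `hbonds`, `rdf`, `rama`, `helix`) run over every
#' tier of the input: either a set of synthetic noise tiers (config block
#' `synthetic`) or one trajectory from disk (config block `input`).  Each
#' stage writes a CSV table with mean and error columns; a JSON manifest
#' records the config hash, package version, seed and any per-stage
#' failures.  Failing stages do not abort the remaining stages.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param outdir output directory (created if absent).
#' @param seed integer seed overriding the config seed.
#' @param stages character vector overriding the config stage list.
#' @return invisibly, the manifest list.
#' @export
run_analysis <- function(config, outdir, seed = NULL, stages = NULL) {
  config <- read_config(config)
  if (is.null(config$synthetic) && is.null(config$input)) {
    stop("config must contain a 'synthetic' or an 'input' block")
  }
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(stages)) {
    stages <- if (is.null(config$stages)) {
      c("rmsd", "rmsf", "hbonds", "rdf", "rama", "helix")
    } else unlist(config$stages)
  }
  unknown <- setdiff(stages, c("rmsd", "rmsf", "hbonds", "rdf", "rama", "helix"))
  if (length(unknown) > 0L) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  data <- if (!is.null(config$synthetic)) synthetic_tiers(config$synthetic, seed)
          else load_input(config$input)
  system <- data$bundle$system
  annotation <- data$bundle$annotation
  trajs <- data$trajectories
  tiers <- names(trajs)
  criterion <- config_criterion(config)
  blk <- config_blocking(config)
  wtrop <- !is.null(annotation) && any(annotation$label == "LOOP")

  exclude <- if (!is.null(annotation) && all(annotation$label == "HELIX")) {
    c("tail7", "head4")
  } else "tail7"
  sel_ca <- select_atoms(system, atoms = "CA", exclude = exclude)
  sel_ca_all <- select_atoms(system, atoms = "CA")

  manifest <- list(config_hash = NA_character_, package = "helixtraj",
                   version = as.character(packageVersion("helixtraj")),
                   seed = seed, stages = stages, tiers = tiers,
                   kind = data$kind, outputs = character(0L),
                   failures = list(), warnings = list())
  cfg_path <- file.path(outdir, "config_used.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))

  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    warns <- character(0L)
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (length(warns) > 0L) manifest$warnings[[name]] <<- warns
    if (inherits(res, "error")) {
      manifest$failures[[name]] <<- conditionMessage(res)
    } else if (is.character(res)) {
      manifest$outputs <<- c(manifest$outputs, basename(res))
    }
    invisible(NULL)
  }

  run_stage("rmsd", function() {
    series <- lapply(tiers, function(tn) rmsd_series(trajs[[tn]], system, sel_ca))
    names(series) <- tiers
    df <- do.call(rbind, lapply(tiers, function(tn) {
      data.frame(tier = tn, time = series[[tn]]$times,
                 rmsd = series[[tn]]$values)
    }))
    out <- write_stage_csv(df, outdir, "rmsd_series.csv")
    summ <- do.call(rbind, lapply(tiers, function(tn) {
      b <- block_average(series[[tn]]$values, times = series[[tn]]$times,
                         window = blk$window, n_blocks = blk$n_blocks)
      data.frame(tier = tn, mean = b$mean, error = b$error)
    }))
    out2 <- write_stage_csv(summ, outdir, "rmsd_summary.csv")
    outs <- c(out, out2)
    if (length(tiers) > 1L) {
      pd <- do.call(rbind, lapply(tiers[-1L], function(tn) {
        p <- percent_increase(series[[tn]], series[[1L]])
        data.frame(tier = tn, time = p$times, percent_d = 100 * p$values,
                   mean_percent_d = 100 * p$mean)
      }))
      outs <- c(outs, write_stage_csv(pd, outdir, "percent_d.csv"))
    }
    outs
  })

  run_stage("rmsf", function() {
    df <- do.call(rbind, lapply(tiers, function(tn) {
      r <- rmsf_per_residue(trajs[[tn]], sel_ca_all, reference = "time_mean",
                            chain_average = TRUE)
      data.frame(tier = tn, res_index = r$res_index, rmsf = r$rmsf)
    }))
    write_stage_csv(df, outdir, "rmsf.csv")
  })

  run_stage("hbonds", function() {
    outs <- character(0L)
    census <- do.call(rbind, lapply(tiers, function(tn) {
      cs <- hbond_census(trajs[[tn]], criterion, window = blk$window,
                         n_blocks = blk$n_blocks)
      rbind(
        data.frame(tier = tn, class = "PP", mean = cs$pp$mean, error = cs$pp$error),
        data.frame(tier = tn, class = "PP_interchain",
                   mean = cs$pp_interchain$mean, error = cs$pp_interchain$error),
        data.frame(tier = tn, class = "PP_intrachain",
                   mean = cs$pp_intrachain$mean, error = cs$pp_intrachain$error),
        data.frame(tier = tn, class = "PP_intrachain_per_residue",
                   mean = cs$intrachain_per_residue, error = NA_real_),
        if (!is.null(cs$pw)) data.frame(tier = tn, class = "PW",
                                        mean = cs$pw$mean, error = cs$pw$error),
        if (!is.null(cs$ww_per_water)) data.frame(tier = tn, class = "WW_per_water",
                                                  mean = cs$ww_per_water$mean,
                                                  error = cs$ww_per_water$error))
    }))
    outs <- c(outs, write_stage_csv(census, outdir, "hbond_census.csv"))
    if (!is.null(annotation)) {
      hh <- do.call(rbind, lapply(tiers, function(tn) {
        h <- helix_i_to_i4(trajs[[tn]], annotation, criterion,
                           window = blk$window, n_blocks = blk$n_blocks)
        cbind(tier = tn, h)
      }))
      outs <- c(outs, write_stage_csv(hh, outdir, "helix_hb.csv"))
      if (wtrop) {
        lb <- do.call(rbind, lapply(tiers, function(tn) {
          l <- loop_bridge_table(trajs[[tn]], annotation, criterion,
                                 window = blk$window, n_blocks = blk$n_blocks)
          cbind(tier = tn, merge(l$table, l$bridges,
                                 by = c("chain_id", "res_index")))
        }))
        outs <- c(outs, write_stage_csv(lb, outdir, "loop_bridge.csv"))
      }
    }
    outs
  })

  run_stage("rdf", function() {
    if (is.null(annotation)) stop("rdf stage needs an annotation with hydrophobic flags")
    grouping <- if (data$kind == "rm6_like") "per_pair" else "per_chain"
    sels <- hydrophobic_selection(system, annotation, grouping)
    rc <- config$rdf
    bw <- if (is.null(rc$bin_width)) 0.02 else rc$bin_width
    rmax <- if (is.null(rc$r_max)) 2.0 else rc$r_max
    # synthetic bundles are aperiodic; normalise on the bounding volume
    vol <- prod(apply(system$xyz, 2L, function(v) diff(range(v)) + 1))
    df <- do.call(rbind, lapply(tiers, function(tn) {
      g <- rdf(trajs[[tn]], sels[[1L]], sels[[2L]], bin_width = bw,
               r_max = rmax, periodic = FALSE, volume = vol)
      data.frame(tier = tn, r = g$r, g = g$g, counts = g$counts)
    }))
    out <- write_stage_csv(df, outdir, "rdf.csv")
    cm <- do.call(rbind, lapply(tiers, function(tn) {
      s <- cm_distance_series(trajs[[tn]], sels[[1L]], sels[[2L]])
      b <- block_average(s$values, times = s$times, window = blk$window,
                         n_blocks = blk$n_blocks)
      data.frame(tier = tn, mean = b$mean, error = b$error)
    }))
    c(out, write_stage_csv(cm, outdir, "cm_distance.csv"))
  })

  run_stage("rama", function() {
    outs <- character(0L)
    rp <- do.call(rbind, lapply(tiers, function(tn) {
      p <- region_percentages(trajs[[tn]], window = blk$window,
                              n_blocks = blk$n_blocks)
      data.frame(tier = tn, region = names(p$percent),
                 percent = as.numeric(p$percent))
    }))
    outs <- c(outs, write_stage_csv(rp, outdir, "rama_percent.csv"))
    if (!is.null(annotation) && nrow(helix_ranges(annotation)) > 0L) {
      mt <- do.call(rbind, lapply(tiers, function(tn) {
        cbind(tier = tn, helix_mean_torsions(trajs[[tn]], annotation,
                                             window = blk$window,
                                             n_blocks = blk$n_blocks))
      }))
      outs <- c(outs, write_stage_csv(mt, outdir, "helix_torsions.csv"))
    }
    outs
  })

  run_stage("helix", function() {
    if (is.null(annotation)) stop("helix stage needs an annotation with helix ranges")
    hm <- do.call(rbind, lapply(tiers, function(tn) {
      cbind(tier = tn, helix_metrics_series(trajs[[tn]], annotation,
                                            window = blk$window,
                                            n_blocks = blk$n_blocks))
    }))
    out <- write_stage_csv(hm, outdir, "helix_metrics.csv")
    hr <- helix_ranges(annotation)
    ree <- do.call(rbind, lapply(tiers, function(tn) {
      do.call(rbind, lapply(seq_len(nrow(hr)), function(h) {
        vals <- vapply(seq_len(n_frames(trajs[[tn]])), function(k) {
          end_to_end(system, hr$chain_id[h],
                     seq(hr$res_start[h], hr$res_end[h]),
                     xyz = trajs[[tn]]$frames[[k]])
        }, numeric(1L))
        b <- block_average(vals, times = trajs[[tn]]$times,
                           window = blk$window, n_blocks = blk$n_blocks)
        data.frame(tier = tn, helix_id = hr$helix_id[h],
                   ree_mean = b$mean, ree_err = b$error)
      }))
    }))
    c(out, write_stage_csv(ree, outdir, "end_to_end.csv"))
  })

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a synthetic fixture set on disk
#'
#' Writes the topology PDB, one multi-model trajectory PDB per noise tier,
#' the region annotation table and a ground-truth JSON (per-residue sigma
#' per tier, seeds, ideal helix parameters) so downstream tests can assert
#' against known inputs.
#'
#' @param config path to a YAML config (block `synthetic`) or a list.
#' @param outdir output directory.
#' @param seed integer seed overriding the config seed.
#' @return invisibly, a list of written paths.
#' @export
generate_fixture <- function(config, outdir, seed = NULL) {
  config <- read_config(config)
  if (is.null(config$synthetic)) stop("fixture generation needs a 'synthetic' block")
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data <- synthetic_tiers(config$synthetic, seed)
  paths <- list()
  paths$topology <- file.path(outdir, "topology.pdb")
  write_pdb(data$bundle$system, paths$topology)
  paths$annotation <- file.path(outdir, "annotation.txt")
  write_annotation(data$bundle$annotation, paths$annotation)
  for (tn in names(data$trajectories)) {
    p <- file.path(outdir, paste0("traj_", tn, ".pdb"))
    write_trajectory(data$trajectories[[tn]], p)
    paths[[paste0("traj_", tn)]] <- p
  }
  helix_sel <- select_atoms(data$bundle$system, atoms = "CA",
                            annotation = data$bundle$annotation,
                            region = if (data$kind == "wtrop_like") "HELIX1" else "HELIX",
                            chains = data$bundle$system$chains[1L])
  hm <- helix_metrics(selection_coords(helix_sel, data$bundle$system))
  truth <- list(kind = data$kind, seed = seed, n_frames = data$n_frames,
                dt = data$dt, sigma = data$sigmas,
                helix = list(d = hm$d, r = hm$r, theta = hm$theta))
  paths$ground_truth <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
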