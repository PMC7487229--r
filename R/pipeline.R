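#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]:
#' a global seed (module seeds are derived deterministically from it),
#' input/output directories, stage toggles and the nested module
#' configurations. Unknown keys are rejected.
#'
#' @param seed Global integer seed.
#' @param input_dir Directory read by non-simulate stages (defaults to
#'   `output_dir`, so a simulate stage feeds the rest).
#' @param output_dir Directory where stage outputs are written.
#' @param stages Character subset of `c("simulate", "score", "domains",
#'   "populations", "cascade")`.
#' @param assays,domains,mesocosms Module configs
#'   ([assay_sim_config()], [domain_sim_config()],
#'   [mesocosm_sim_config()]); their seeds are overwritten with
#'   module-derived seeds.
#' @param n_boot Bootstrap replicates for the score stage's
#'   repeatability estimate.
#' @param n_perm Permutations for the cascade stage's label test.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       output_dir = tempfile("shybold_run_"),
                       input_dir = output_dir,
                       stages = c("simulate", "score", "domains",
                                  "populations", "cascade"),
                       assays = assay_sim_config(),
                       domains = domain_sim_config(),
                       mesocosms = mesocosm_sim_config(),
                       n_boot = 100,
                       n_perm = 199) {
  known <- c("simulate", "score", "domains", "populations", "cascade")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  assays$seed <- derive_seed(seed, "synthgrass_assays")
  domains$seed <- derive_seed(seed, "synthgrass_domains")
  mesocosms$seed <- derive_seed(seed, "synthgrass_mesocosms")
  cfg <- list(seed = as.integer(seed), input_dir = input_dir,
              output_dir = output_dir, stages = stages,
              assays = assays, domains = domains, mesocosms = mesocosms,
              n_boot = n_boot, n_perm = n_perm)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields (`seed`, `stages`, `n_boot`, `n_perm`, directories) and
#' nested module sections (`assays`, `domains`, `mesocosms`) override
#' the defaults of [run_config()]; unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "input_dir", "output_dir", "stages", "assays",
             "domains", "mesocosms", "n_boot", "n_perm")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- y[intersect(names(y), c("seed", "input_dir", "output_dir",
                                  "stages", "n_boot", "n_perm"))]
  for (mod in c("assays", "domains", "mesocosms")) {
    if (!is.null(y[[mod]])) {
      ctor <- switch(mod, assays = assay_sim_config,
                     domains = domain_sim_config,
                     mesocosms = mesocosm_sim_config)
      extra <- y[[mod]]
      if (mod == "assays" && !is.null(extra$context_shifts)) {
        extra$context_shifts <- unlist(extra$context_shifts)
      }
      if (mod == "mesocosms") {
        if (!is.null(extra$baseline_biomass)) {
          extra$baseline_biomass <- unlist(extra$baseline_biomass)
        }
        if (!is.null(extra$herbivory_effects)) {
          extra$herbivory_effects <- lapply(extra$herbivory_effects, unlist)
        }
      }
      args[[mod]] <- do.call(ctor, extra)
    }
  }
  do.call(run_config, args)
}

#' Derive a module seed from the global seed
#'
#' Deterministic 31-bit hash of the global seed and a module name, so
#' each module gets an independent but reproducible stream.
#'
#' @param seed Global integer seed.
#' @param module Module name.
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(seed, module) {
  h <- as.numeric(seed) %% 2147483647
  for (k in utf8ToInt(module)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

.write_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  path
}

#' Validate an input file against a pipeline schema
#'
#' Checks column presence, types and value ranges for the pipeline's
#' three CSV dialects: `trajectories` (15 one-minute positions per
#' individual x context x round, integer grid coordinates), `heights`
#' (heights within `[0, 88]` cm) and `mesocosms` (all five treatments
#' present in every block, survival in 0..5, nonnegative biomass).
#'
#' @param path CSV file to check.
#' @param schema One of `"trajectories"`, `"heights"`, `"mesocosms"`.
#' @return A data frame report with columns `check` and `message`; zero
#'   rows means the file is valid.
#' @export
validate_inputs <- function(path, schema = c("trajectories", "heights",
                                             "mesocosms")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  bad <- list()
  note <- function(check, message) {
    bad[[length(bad) + 1L]] <<- data.frame(check = check, message = message)
  }
  need <- switch(schema,
                 trajectories = c("individual_id", "context", "minute",
                                  "x", "y", "assay_round"),
                 heights = c("individual_id", "personality", "context",
                             "time_index", "height_cm", "substrate",
                             "foraging"),
                 mesocosms = c("block_id", "treatment", "survival"))
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    note("columns", paste("missing column(s):",
                          paste(missing_cols, collapse = ", ")))
    out <- do.call(rbind, bad)
    return(out)
  }
  if (schema == "trajectories") {
    if (any(d$x != round(d$x) | d$y != round(d$y))) {
      note("grid", "x/y must be integer 1-cm grid cells")
    }
    cnt <- table(interaction(d$individual_id, d$context, d$assay_round,
                             drop = TRUE))
    wrong <- names(cnt)[cnt != 15]
    if (length(wrong)) {
      note("positions", paste0("expected 15 positions per assay; offending: ",
                               paste(utils::head(wrong, 5), collapse = ", ")))
    }
  } else if (schema == "heights") {
    out_of_range <- d$height_cm < 0 | d$height_cm > 88
    if (any(out_of_range)) {
      note("range", paste(sum(out_of_range),
                          "height(s) outside [0, 88] cm"))
    }
  } else {
    expected <- c("control", "shy", "bold", "shy_pred", "bold_pred")
    for (b in unique(d$block_id)) {
      have <- d$treatment[d$block_id == b]
      if (!setequal(have, expected) || length(have) != 5) {
        note("design", paste("block", b,
                             "does not contain each of the 5 treatments exactly once"))
      }
    }
    sv <- d$survival[d$treatment != "control"]
    if (any(!is.na(sv) & (sv < 0 | sv > 5))) {
      note("survival", "survival must be in 0..5")
    }
    bio <- grep("^biomass_", names(d), value = TRUE)
    if (!length(bio)) note("columns", "no biomass_<group> columns")
    for (bc in bio) {
      if (any(d[[bc]] < 0)) note("biomass", paste(bc, "has negative values"))
    }
  }
  if (!length(bad)) {
    data.frame(check = character(0), message = character(0))
  } else {
    do.call(rbind, bad)
  }
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order: `simulate` (write
#' trajectories.csv, heights.csv, mesocosms.csv), `score` (activity
#' scores, quartile classification -> personality.csv, blocks.csv,
#' repeatability.json), `domains` (heights -> domains.json),
#' `populations` (cohort summary -> populations.csv) and `cascade`
#' (mesocosms -> impacts.csv, trophic_results.json). A manifest
#' (seed, package version, config digest, input/output checksums) is
#' written to manifest.json; reruns on identical config and inputs
#' produce identical outputs and manifest.
#'
#' @param cfg A [run_config()] or path to a YAML config file.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  inputs <- character(0)
  path_in <- function(f) file.path(cfg$input_dir, f)
  path_out <- function(f) file.path(cfg$output_dir, f)
  stage_log <- function(s) message("[shybold] stage: ", s)

  if ("simulate" %in% cfg$stages) {
    stage_log("simulate")
    outputs <- c(outputs,
                 .write_csv(gen_assay_dataset(cfg$assays),
                            path_out("trajectories.csv")),
                 .write_csv(gen_height_observations(cfg$domains),
                            path_out("heights.csv")),
                 .write_csv(gen_mesocosm_dataset(cfg$mesocosms),
                            path_out("mesocosms.csv")))
  }

  if ("score" %in% cfg$stages) {
    stage_log("score")
    f <- path_in("trajectories.csv")
    if (!file.exists(f)) {
      stop("score stage requires ", f,
           " (enable the simulate stage or provide it)", call. = FALSE)
    }
    inputs <- c(inputs, f)
    traj <- utils::read.csv(f)
    at <- activity_table(traj)
    ps <- classify_quartiles(personality_scores(at$scores))
    q <- attr(ps, "quartiles")
    ps$q1 <- q[["q1"]]
    ps$q3 <- q[["q3"]]
    at$blocks$log_activity <- log1p(at$blocks$activity)
    rpt <- estimate_repeatability(at$blocks, value = "log_activity",
                                  grouping = "across_contexts",
                                  n_boot = cfg$n_boot,
                                  seed = derive_seed(cfg$seed, "boot"))
    outputs <- c(outputs,
                 .write_csv(ps, path_out("personality.csv")),
                 .write_csv(at$blocks, path_out("blocks.csv")))
    jsonlite::write_json(
      list(R = rpt$R, se = rpt$se, ci = rpt$ci, n_boot = rpt$n_boot,
           grouping = rpt$grouping, scale = rpt$scale,
           singular = rpt$singular),
      path_out("repeatability.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, path_out("repeatability.json"))
  }

  if ("domains" %in% cfg$stages) {
    stage_log("domains")
    f <- path_in("heights.csv")
    if (!file.exists(f)) {
      stop("domains stage requires ", f,
           " (enable the simulate stage or provide it)", call. = FALSE)
    }
    inputs <- c(inputs, f)
    obs <- utils::read.csv(f)
    rep_dom <- domain_report(obs, canopy_max = cfg$domains$canopy_max)
    jsonlite::write_json(
      list(overlaps = rep_dom$overlaps,
           bins = lapply(rep_dom$uds[c("shy", "bold")], function(u) {
             list(bin_edges = u$bin_edges, counts = u$counts, p = u$p)
           })),
      path_out("domains.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, path_out("domains.json"))
  }

  if ("populations" %in% cfg$stages) {
    stage_log("populations")
    f <- path_in("trajectories.csv")
    if (!file.exists(f)) {
      stop("populations stage requires ", f, call. = FALSE)
    }
    traj <- utils::read.csv(f)
    at <- activity_table(traj)
    ps <- population_summary(at$scores, mesocosm_id = "cohort",
                             phase = "pre")
    outputs <- c(outputs,
                 .write_csv(data.frame(mesocosm_id = ps$mesocosm_id,
                                       phase = ps$phase,
                                       mean_personality = ps$mean_personality,
                                       crp_variance = ps$crp_variance,
                                       n = ps$n),
                            path_out("populations.csv")))
  }

  if ("cascade" %in% cfg$stages) {
    stage_log("cascade")
    f <- path_in("mesocosms.csv")
    if (!file.exists(f)) {
      stop("cascade stage requires ", f,
           " (enable the simulate stage or provide it)", call. = FALSE)
    }
    inputs <- c(inputs, f)
    rec <- utils::read.csv(f)
    impacts <- standardize_biomass(rec)
    groups <- unique(impacts$group)
    models <- lapply(groups, function(g) {
      m <- fit_trophic_model(impacts, g)
      pt <- permute_labels(impacts, g, term = "personality",
                           n_perm = cfg$n_perm,
                           seed = derive_seed(cfg$seed, paste0("perm_", g)))
      list(group = g, terms = m$terms,
           random_block_variance = m$random_block_variance,
           converged = m$converged,
           permutation = list(term = pt$term, observed = pt$observed,
                              p_perm = pt$p_perm, n_perm = pt$n_perm))
    })
    names(models) <- groups
    outputs <- c(outputs, .write_csv(impacts, path_out("impacts.csv")))
    jsonlite::write_json(models, path_out("trophic_results.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, path_out("trophic_results.json"))
  }

  manifest <- list(
    package = "shybold",
    version = as.character(utils::packageVersion("shybold")),
    seed = cfg$seed,
    stages = cfg$stages,
    config_digest = .digest_config(cfg),
    inputs = .checksums(unique(inputs)),
    outputs = .checksums(unique(outputs)))
  jsonlite::write_json(manifest, path_out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.checksums <- function(paths) {
  if (!length(paths)) return(stats::setNames(list(), character(0)))
  sums <- tools::md5sum(paths)
  as.list(stats::setNames(unname(sums), basename(paths)))
}

.digest_config <- function(cfg) {
  # stable digest without the run-specific directories
  c2 <- cfg
  c2$input_dir <- c2$output_dir <- NULL
  txt <- paste(utils::capture.output(utils::str(c2, digits.d = 12)),
               collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
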