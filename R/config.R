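#' Model and synapse preset registry
#'
#' Named parameter sets shipped with the package (a plain-text YAML registry
#' under `extdata`), so experiments and tests reference presets rather than
#' magic numbers.  Neuron presets are bursting parameterisations of each
#' library model; synapse presets include the standard hybrid-circuit
#' validation wiring: a slow inhibitory graded synapse model-to-living
#' (g = 0.2 uS, threshold 15% and slope 1% of the presynaptic amplitude
#' range, kinetics k1 = 14, k2 = 4 1/s; g = 0.1 uS when the model is
#' Hindmarsh-Rose) and a fast inhibitory graded synapse living-to-model
#' (threshold 50%, slope 5%, conductance 0.8 uS for Izhikevich and the
#' Ghigliazza-Holmes-style model, 1.0 uS for Hindmarsh-Rose, 0.2 uS for
#' Rulkov).
#'
#' @param name Preset name; see `preset_registry()` for the available names.
#' @return `neuron_preset()` returns a `neuron_model`; `synapse_preset()` a
#'   `synapse_model`; `preset_registry()` the full parsed registry list.
#' @export
preset_registry <- function() {
  path <- system.file("extdata", "presets.yaml", package = "hybridclamp")
  if (path == "") path <- file.path("inst", "extdata", "presets.yaml")
  yaml::read_yaml(path)
}

#' @rdname preset_registry
#' @export
neuron_preset <- function(name) {
  reg <- preset_registry()$neurons
  if (is.null(reg[[name]])) {
    stop_bad(sprintf("unknown neuron preset '%s' (available: %s)", name,
                     paste(names(reg), collapse = ", ")))
  }
  spec <- reg[[name]]
  build_neuron(spec$type, spec[setdiff(names(spec), "type")])
}

build_neuron <- function(type, params) {
  ctor <- switch(type,
                 rulkov = neuron_rulkov,
                 izhikevich = neuron_izhikevich,
                 hindmarsh_rose = neuron_hindmarsh_rose,
                 ghigliazza_holmes = neuron_ghigliazza_holmes,
                 wang = neuron_wang,
                 stop_bad(sprintf("unknown neuron model type '%s'", type)))
  do.call(ctor, params)
}

#' @rdname preset_registry
#' @export
synapse_preset <- function(name) {
  reg <- preset_registry()$synapses
  if (is.null(reg[[name]])) {
    stop_bad(sprintf("unknown synapse preset '%s' (available: %s)", name,
                     paste(names(reg), collapse = ", ")))
  }
  spec <- reg[[name]]
  build_synapse(spec$type, spec[setdiff(names(spec), "type")])
}

build_synapse <- function(type, params) {
  ctor <- switch(type,
                 electrical = synapse_electrical,
                 graded = synapse_graded,
                 chemical = synapse_chemical,
                 stop_bad(sprintf("unknown synapse type '%s'", type)))
  do.call(ctor, params)
}

#' The standard bidirectional validation wiring for a given model
#'
#' Convenience lookup of the synapse pair used in hybrid-circuit validation:
#' slow inhibitory graded model-to-living and fast inhibitory graded
#' living-to-model, with the conductance matched to the neuron model in use.
#'
#' @param model_name One of `"rulkov"`, `"izhikevich"`, `"hindmarsh_rose"`,
#'   `"ghigliazza_holmes"`.
#' @return List with elements `model_to_live` and `live_to_model`.
#' @export
validation_wiring <- function(model_name) {
  slow <- if (model_name == "hindmarsh_rose") "slow_inhibitory_hr" else
    "slow_inhibitory"
  fast <- switch(model_name,
                 rulkov = "fast_inhibitory_rulkov",
                 izhikevich = "fast_inhibitory_izhikevich",
                 hindmarsh_rose = "fast_inhibitory_hindmarsh_rose",
                 ghigliazza_holmes = "fast_inhibitory_ghigliazza_holmes",
                 stop_bad(sprintf("no validation wiring for model '%s'",
                                  model_name)))
  list(model_to_live = synapse_preset(slow), live_to_model = synapse_preset(fast))
}

#' Experiment configuration
#'
#' Full description of a hybrid-circuit run: sampling rate, the three phase
#' durations (pre-control, coupled, post-control), the neuron model and the
#' two synapses, calibration and preparation settings, acquisition scaling,
#' integrator, seed and output paths.  Configurations round-trip losslessly
#' through the XML reader/writer.
#'
#' @param fs Sampling frequency (Hz).
#' @param pre_s,coupled_s,post_s Phase durations (s).
#' @param model A `neuron_model`, or a neuron preset name.
#' @param syn_model_to_live,syn_live_to_model `synapse_model`s or synapse
#'   preset names; `NULL` selects the standard validation wiring for the
#'   model.
#' @param target_burst Burst-duration target (s) for model calibration, or
#'   `"auto"` to match the living neuron's observed burst duration.
#' @param integrator An [integrator_spec()].
#' @param scaling An [acquisition_scaling()].
#' @param prep_noise_sd,prep_drift_mv_per_min,prep_period_s,prep_soma_tau_s
#'   Virtual preparation settings (noise sd in mV, drift in mV/min, burst
#'   period s, somatic low-pass time constant s).
#' @param live_range Nominal preparation output range (mV).
#' @param drift_compensation Enable drift compensation in the loop.
#' @param drift_tau_s,drift_window_s Drift estimator time constant and
#'   window (s).
#' @param seed Integer seed for all randomness of the run.
#' @param clock `"virtual"` or `"wall"`.
#' @param record_every Interval-record thinning factor.
#' @param output_dir Directory for trace/latency/log files, or `NULL` to
#'   keep results in memory only.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(fs = 10000, pre_s = 10, coupled_s = 60,
                              post_s = 10, model = "izhikevich_bursting",
                              syn_model_to_live = NULL,
                              syn_live_to_model = NULL,
                              target_burst = "auto",
                              integrator = integrator_spec("rk4"),
                              scaling = acquisition_scaling(),
                              prep_noise_sd = 0.5,
                              prep_drift_mv_per_min = 0,
                              prep_period_s = 1,
                              prep_soma_tau_s = 0.02,
                              live_range = c(-60, -25),
                              drift_compensation = FALSE,
                              drift_tau_s = 2, drift_window_s = 1,
                              seed = 1L, clock = "virtual",
                              record_every = 1L, output_dir = NULL,
                              engine = c("auto", "fused", "loop")) {
  engine <- match.arg(engine)
  if (is.character(model)) model <- neuron_preset(model)
  if (is.null(syn_model_to_live) || is.null(syn_live_to_model)) {
    wiring <- validation_wiring(model$name)
    if (is.null(syn_model_to_live)) syn_model_to_live <- wiring$model_to_live
    if (is.null(syn_live_to_model)) syn_live_to_model <- wiring$live_to_model
  }
  if (is.character(syn_model_to_live)) syn_model_to_live <- synapse_preset(syn_model_to_live)
  if (is.character(syn_live_to_model)) syn_live_to_model <- synapse_preset(syn_live_to_model)
  stopifnot(pre_s >= 0, coupled_s >= 0, post_s >= 0, fs > 0)
  structure(list(
    fs = fs, pre_s = pre_s, coupled_s = coupled_s, post_s = post_s,
    model = model, syn_model_to_live = syn_model_to_live,
    syn_live_to_model = syn_live_to_model, target_burst = target_burst,
    integrator = integrator, scaling = scaling,
    prep_noise_sd = prep_noise_sd,
    prep_drift_mv_per_min = prep_drift_mv_per_min,
    prep_period_s = prep_period_s, prep_soma_tau_s = prep_soma_tau_s,
    live_range = live_range,
    drift_compensation = drift_compensation, drift_tau_s = drift_tau_s,
    drift_window_s = drift_window_s, seed = as.integer(seed), clock = clock,
    record_every = as.integer(record_every), output_dir = output_dir,
    engine = engine),
    class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %g Hz | %g s pre / %g s coupled / %g s post | seed %d (%s clock)\n",
              x$fs, x$pre_s, x$coupled_s, x$post_s, x$seed, x$clock))
  cat(sprintf("  model: %s | m->l: %s g=%g uS | l->m: %s g=%g uS\n",
              x$model$name, x$syn_model_to_live$type, x$syn_model_to_live$g,
              x$syn_live_to_model$type, x$syn_live_to_model$g))
  invisible(x)
}

#' Read and write experiment configurations as XML
#'
#' The XML dialect is original to this package and versioned; a schema ships
#' under `extdata/experiment-config.xsd`, together with one example
#' configuration per validation model under `extdata/configs/`.
#'
#' @param path XML file path.
#' @return `read_experiment_config()` returns an `experiment_config`;
#'   `write_experiment_config()` returns `path` invisibly.
#' @export
read_experiment_config <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "hybridclamp_experiment") {
    stop_bad("not a hybridclamp experiment configuration",
             class = "hybridclamp_config")
  }
  num_attr <- function(node, a) as.numeric(xml2::xml_attr(node, a))
  exp <- xml2::xml_find_first(doc, "./experiment")
  neuron <- xml2::xml_find_first(doc, "./neuron")
  n_params <- xml2::xml_find_all(neuron, "./param")
  pars <- as.list(as.numeric(xml2::xml_attr(n_params, "value")))
  names(pars) <- xml2::xml_attr(n_params, "name")
  model <- build_neuron(xml2::xml_attr(neuron, "type"), pars)
  syn_node <- function(dir) {
    node <- xml2::xml_find_first(doc,
                                 sprintf("./synapse[@direction='%s']", dir))
    if (inherits(node, "xml_missing")) {
      stop_bad(sprintf("missing <synapse direction='%s'>", dir),
               class = "hybridclamp_config")
    }
    s_params <- xml2::xml_find_all(node, "./param")
    sp <- as.list(as.numeric(xml2::xml_attr(s_params, "value")))
    names(sp) <- xml2::xml_attr(s_params, "name")
    type <- xml2::xml_attr(node, "type")
    if (type == "graded") sp$mode <- xml2::xml_attr(node, "mode")
    build_synapse(type, sp)
  }
  calib <- xml2::xml_find_first(doc, "./calibration")
  scal <- xml2::xml_find_first(doc, "./scaling")
  prep <- xml2::xml_find_first(doc, "./preparation")
  integ <- xml2::xml_find_first(doc, "./integrator")
  tb <- xml2::xml_attr(calib, "target_burst_s")
  experiment_config(
    fs = num_attr(exp, "frequency_hz"),
    pre_s = num_attr(exp, "pre_control_s"),
    coupled_s = num_attr(exp, "coupled_s"),
    post_s = num_attr(exp, "post_control_s"),
    model = model,
    syn_model_to_live = syn_node("model_to_live"),
    syn_live_to_model = syn_node("live_to_model"),
    target_burst = if (identical(tb, "auto")) "auto" else as.numeric(tb),
    integrator = integrator_spec(xml2::xml_attr(integ, "method"),
                                 dt = num_attr(integ, "dt")),
    scaling = acquisition_scaling(num_attr(scal, "input_factor"),
                                  num_attr(scal, "na_per_v")),
    prep_noise_sd = num_attr(prep, "noise_sd_mv"),
    prep_drift_mv_per_min = num_attr(prep, "drift_mv_per_min"),
    prep_period_s = num_attr(prep, "burst_period_s"),
    prep_soma_tau_s = num_attr(prep, "soma_tau_s"),
    live_range = c(num_attr(prep, "range_min_mv"),
                   num_attr(prep, "range_max_mv")),
    drift_compensation = identical(xml2::xml_attr(calib, "drift_compensation"),
                                   "true"),
    drift_tau_s = num_attr(calib, "drift_tau_s"),
    drift_window_s = num_attr(calib, "drift_window_s"),
    seed = as.integer(num_attr(exp, "seed")),
    clock = xml2::xml_attr(exp, "clock"),
    record_every = as.integer(num_attr(exp, "record_every")))
}

#' @rdname read_experiment_config
#' @param config An `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  doc <- xml2::xml_new_root("hybridclamp_experiment", version = "1")
  xml2::xml_add_child(doc, "experiment",
                      frequency_hz = fmt_num(config$fs),
                      pre_control_s = fmt_num(config$pre_s),
                      coupled_s = fmt_num(config$coupled_s),
                      post_control_s = fmt_num(config$post_s),
                      seed = fmt_num(config$seed),
                      clock = config$clock,
                      record_every = fmt_num(config$record_every))
  neuron <- xml2::xml_add_child(doc, "neuron", type = config$model$name)
  add_params(neuron, config$model$params)
  for (dir in c("model_to_live", "live_to_model")) {
    syn <- config[[paste0("syn_", dir)]]
    type <- if (startsWith(syn$type, "graded")) "graded" else syn$type
    node <- xml2::xml_add_child(doc, "synapse", direction = dir, type = type)
    keep <- setdiff(names(syn), c("type", "mode"))
    if (type == "graded") xml2::xml_set_attr(node, "mode", syn$mode)
    add_params(node, syn[keep])
  }
  xml2::xml_add_child(doc, "calibration",
                      target_burst_s = if (identical(config$target_burst, "auto"))
                        "auto" else fmt_num(config$target_burst),
                      drift_compensation = tolower(as.character(config$drift_compensation)),
                      drift_tau_s = fmt_num(config$drift_tau_s),
                      drift_window_s = fmt_num(config$drift_window_s))
  xml2::xml_add_child(doc, "scaling",
                      input_factor = fmt_num(config$scaling$input_factor),
                      na_per_v = fmt_num(config$scaling$na_per_v))
  xml2::xml_add_child(doc, "integrator",
                      method = config$integrator$method,
                      dt = fmt_num(config$integrator$dt))
  xml2::xml_add_child(doc, "preparation",
                      noise_sd_mv = fmt_num(config$prep_noise_sd),
                      drift_mv_per_min = fmt_num(config$prep_drift_mv_per_min),
                      burst_period_s = fmt_num(config$prep_period_s),
                      soma_tau_s = fmt_num(config$prep_soma_tau_s),
                      range_min_mv = fmt_num(config$live_range[1]),
                      range_max_mv = fmt_num(config$live_range[2]))
  xml2::write_xml(doc, path)
  invisible(path)
}

fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

add_params <- function(node, params) {
  for (nm in names(params)) {
    val <- params[[nm]]
    if (is.numeric(val) && !anyNA(val)) {
      xml2::xml_add_child(node, "param", name = nm, value = fmt_num(val))
    }
  }
  invisible(node)
}
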