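# Named parameter presets for the hybridclamp model library.
#
# Neuron presets are the package's bursting parameterisations: the paper
# families these models come from do not fix a unique parameter set, so each
# preset was placed in a regular bursting regime (verified by the burst
# detector) and is shipped here so experiments and tests reference names,
# not magic numbers.
neurons:
  rulkov_bursting:
    type: rulkov
    alpha: 5.0
    sigma: 0.05
    mu: 0.001
  izhikevich_bursting:
    type: izhikevich
    a: 0.028
    b: 0.2
    c: -50.0
    d: 2.0
    peak: 30.0
    I: 15.0
  hindmarsh_rose_bursting:
    type: hindmarsh_rose
    b: 3.0
    I: 3.0
    r: 0.0025
    s: 4.0
    x_rest: -1.6
  ghigliazza_holmes_bursting:
    type: ghigliazza_holmes
    C: 20.0
    g_ca: 3.6
    g_k: 6.0
    g_ks: 4.0
    g_l: 0.1
    e_ca: 25.0
    e_k: -75.0
    e_l: -40.0
    I: 1.0
    vm_half: -24.0
    vm_slope: 4.5
    vw_half: -12.0
    vw_slope: 4.0
    vc_half: -40.0
    vc_slope: 2.0
    tau_w: 15.0
    tau_c: 1600.0
    tau_c_rest: 500.0
  wang_bursting:
    type: wang
    C: 1.0
    g_na: 120.0
    g_k: 36.0
    g_l: 0.3
    g_ks: 2.0
    e_na: 50.0
    e_k: -77.0
    e_l: -54.4
    I: 12.0
    vq_half: -30.0
    vq_slope: 5.0
    tau_q: 300.0

# Synapse presets of the standard bidirectional validation wiring:
# slow inhibitory graded model->living, fast inhibitory graded
# living->model, conductances matched to the neuron model in use.
# e_syn is left unset (resolved at calibration time to the observed
# minimum of the postsynaptic signal, guaranteeing inhibition).
synapses:
  slow_inhibitory:
    type: graded
    mode: slow
    g: 0.2
    v_threshold_pct: 15.0
    slope_pct: 1.0
    k1: 14.0
    k2: 4.0
  slow_inhibitory_hr:
    type: graded
    mode: slow
    g: 0.1
    v_threshold_pct: 15.0
    slope_pct: 1.0
    k1: 14.0
    k2: 4.0
  fast_inhibitory_izhikevich:
    type: graded
    mode: fast
    g: 0.8
    v_threshold_pct: 50.0
    slope_pct: 5.0
  fast_inhibitory_ghigliazza_holmes:
    type: graded
    mode: fast
    g: 0.8
    v_threshold_pct: 50.0
    slope_pct: 5.0
  fast_inhibitory_hindmarsh_rose:
    type: graded
    mode: fast
    g: 1.0
    v_threshold_pct: 50.0
    slope_pct: 5.0
  fast_inhibitory_rulkov:
    type: graded
    mode: fast
    g: 0.2
    v_threshold_pct: 50.0
    slope_pct: 5.0
  electrical_default:
    type: electrical
    g: 0.1
  chemical_default:
    type: chemical
    g: 0.2
    e_syn: -70.0
    alpha: 0.94
    beta: 0.18
    t_max: 1.0
    pulse_duration: 1.0
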