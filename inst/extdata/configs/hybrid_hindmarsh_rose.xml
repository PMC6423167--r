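<?xml version="1.0" encoding="UTF-8"?>
<hybridclamp_experiment version="1">
  <experiment frequency_hz="10000" pre_control_s="10" coupled_s="60" post_control_s="10" seed="1" clock="virtual" record_every="1"/>
  <neuron type="hindmarsh_rose">
    <param name="b" value="3"/>
    <param name="I" value="3"/>
    <param name="r" value="0.0025000000000000001"/>
    <param name="s" value="4"/>
    <param name="x_rest" value="-1.6000000000000001"/>
  </neuron>
  <synapse direction="model_to_live" type="graded" mode="slow">
    <param name="g" value="0.10000000000000001"/>
    <param name="v_threshold_pct" value="15"/>
    <param name="slope_pct" value="1"/>
    <param name="k1" value="14"/>
    <param name="k2" value="4"/>
  </synapse>
  <synapse direction="live_to_model" type="graded" mode="fast">
    <param name="g" value="1"/>
    <param name="v_threshold_pct" value="50"/>
    <param name="slope_pct" value="5"/>
    <param name="k1" value="14"/>
    <param name="k2" value="4"/>
  </synapse>
  <calibration target_burst_s="auto" drift_compensation="false" drift_tau_s="2" drift_window_s="1"/>
  <scaling input_factor="100" na_per_v="10"/>
  <integrator method="rk4" dt="0.01"/>
  <preparation noise_sd_mv="0.5" drift_mv_per_min="0" burst_period_s="1" soma_tau_s="0.02" range_min_mv="-60" range_max_mv="-25"/>
</hybridclamp_experiment>
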