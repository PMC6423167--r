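<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema (version 1) for hybridclamp experiment configuration files. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:element name="hybridclamp_experiment">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="experiment">
          <xs:complexType>
            <xs:attribute name="frequency_hz" type="xs:double" use="required"/>
            <xs:attribute name="pre_control_s" type="xs:double" use="required"/>
            <xs:attribute name="coupled_s" type="xs:double" use="required"/>
            <xs:attribute name="post_control_s" type="xs:double" use="required"/>
            <xs:attribute name="seed" type="xs:integer" use="required"/>
            <xs:attribute name="clock" type="clockKind" use="required"/>
            <xs:attribute name="record_every" type="xs:positiveInteger" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="neuron" type="paramNode"/>
        <xs:element name="synapse" minOccurs="2" maxOccurs="2">
          <xs:complexType>
            <xs:complexContent>
              <xs:extension base="paramNode">
                <xs:attribute name="direction" type="synDirection" use="required"/>
                <xs:attribute name="mode" type="xs:string"/>
              </xs:extension>
            </xs:complexContent>
          </xs:complexType>
        </xs:element>
        <xs:element name="calibration">
          <xs:complexType>
            <xs:attribute name="target_burst_s" type="xs:string" use="required"/>
            <xs:attribute name="drift_compensation" type="xs:string" use="required"/>
            <xs:attribute name="drift_tau_s" type="xs:double" use="required"/>
            <xs:attribute name="drift_window_s" type="xs:double" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="scaling">
          <xs:complexType>
            <xs:attribute name="input_factor" type="xs:double" use="required"/>
            <xs:attribute name="na_per_v" type="xs:double" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="integrator">
          <xs:complexType>
            <xs:attribute name="method" type="xs:string" use="required"/>
            <xs:attribute name="dt" type="xs:double" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="preparation">
          <xs:complexType>
            <xs:attribute name="noise_sd_mv" type="xs:double" use="required"/>
            <xs:attribute name="drift_mv_per_min" type="xs:double" use="required"/>
            <xs:attribute name="burst_period_s" type="xs:double" use="required"/>
            <xs:attribute name="soma_tau_s" type="xs:double" use="required"/>
            <xs:attribute name="range_min_mv" type="xs:double" use="required"/>
            <xs:attribute name="range_max_mv" type="xs:double" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="version" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
  <xs:complexType name="paramNode">
    <xs:sequence>
      <xs:element name="param" minOccurs="0" maxOccurs="unbounded">
        <xs:complexType>
          <xs:attribute name="name" type="xs:string" use="required"/>
          <xs:attribute name="value" type="xs:double" use="required"/>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
    <xs:attribute name="type" type="xs:string" use="required"/>
  </xs:complexType>
  <xs:simpleType name="clockKind">
    <xs:restriction base="xs:string">
      <xs:enumeration value="virtual"/>
      <xs:enumeration value="wall"/>
    </xs:restriction>
  </xs:simpleType>
  <xs:simpleType name="synDirection">
    <xs:restriction base="xs:string">
      <xs:enumeration value="model_to_live"/>
      <xs:enumeration value="live_to_model"/>
    </xs:restriction>
  </xs:simpleType>
</xs:schema>
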