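# Six-current stomatogastric-ganglion (STG) neuron model.
#
# Gating kinetics of the crustacean STG model cell (Turrigiano/Liu lineage):
# each gate has a Boltzmann steady state and a sigmoidal (or bell-shaped)
# voltage-dependent time constant. Units: mV, ms, mS/cm2, uA/cm2, uM.
# The calcium reversal potential is fixed at +120 mV. The maximal
# conductances below are the reference densities of the bursting cell.
# The calcium pool integrates the two calcium currents with a conversion of
# 9.4 uM per uA/cm2 (14.96 uM/nA over a 0.628e-3 cm2 membrane).
name: stg
capacitance: 1
i_app: 0
v_range: [-80.0, 50.0]
leak: {g: 0.01, erev: -50.0}
calcium: {tau: 200.0, f: 9.4, ca0: 0.05}
designation: {fast: Na.m, slow: Kd.m, ultraslow: CaS.h}
currents:
  - name: Na
    gbar: 700.0
    erev: 50.0
    calcium_carrying: false
    activation:
      exponent: 3
      inf: {form: boltzmann, params: {half: -25.5, slope: 5.29}}
      tau: {form: tau_sigmoid, params: {base: 2.64, amp: -2.52, half: -120.0, slope: 25.0}}
    inactivation:
      exponent: 1
      inf: {form: boltzmann, params: {half: -48.9, slope: -5.18}}
      tau: {form: tau_double_sigmoid, params: {amp: 1.34, half1: -62.9, slope1: 10.0, base2: 1.5, half2: -34.9, slope2: 3.6}}
  - name: CaT
    gbar: 2.0
    erev: 120.0
    calcium_carrying: true
    activation:
      exponent: 3
      inf: {form: boltzmann, params: {half: -27.1, slope: 7.2}}
      tau: {form: tau_sigmoid, params: {base: 43.4, amp: -42.6, half: -68.1, slope: 20.5}}
    inactivation:
      exponent: 1
      inf: {form: boltzmann, params: {half: -32.1, slope: -5.5}}
      tau: {form: tau_sigmoid, params: {base: 210.0, amp: -179.6, half: -55.0, slope: 16.9}}
  - name: CaS
    gbar: 4.0
    erev: 120.0
    calcium_carrying: true
    activation:
      exponent: 3
      inf: {form: boltzmann, params: {half: -33.0, slope: 8.1}}
      tau: {form: tau_biexp, params: {base: 2.8, amp: 14.0, half1: -27.0, slope1: 10.0, half2: -70.0, slope2: -13.0}}
    inactivation:
      exponent: 1
      inf: {form: boltzmann, params: {half: -60.0, slope: -6.2}}
      tau: {form: tau_biexp, params: {base: 120.0, amp: 300.0, half1: -55.0, slope1: 9.0, half2: -65.0, slope2: -16.0}}
  - name: A
    gbar: 50.0
    erev: -80.0
    calcium_carrying: false
    activation:
      exponent: 3
      inf: {form: boltzmann, params: {half: -27.2, slope: 8.7}}
      tau: {form: tau_sigmoid, params: {base: 23.2, amp: -20.8, half: -32.9, slope: 15.2}}
    inactivation:
      exponent: 1
      inf: {form: boltzmann, params: {half: -56.9, slope: -4.9}}
      tau: {form: tau_sigmoid, params: {base: 77.2, amp: -58.4, half: -38.9, slope: 26.5}}
  - name: KCa
    gbar: 40.0
    erev: -80.0
    calcium_carrying: false
    activation:
      exponent: 4
      inf: {form: ca_boltzmann, params: {half: -28.3, slope: 12.6, kd: 3.0}}
      tau: {form: tau_sigmoid, params: {base: 180.6, amp: -150.2, half: -46.0, slope: 22.7}}
  - name: Kd
    gbar: 70.0
    erev: -80.0
    calcium_carrying: false
    activation:
      exponent: 4
      inf: {form: boltzmann, params: {half: -12.3, slope: 11.8}}
      tau: {form: tau_sigmoid, params: {base: 14.4, amp: -12.8, half: -28.3, slope: 19.2}}
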