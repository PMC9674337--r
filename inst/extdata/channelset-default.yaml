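# Reduced LGMD channel set, version 1.
# Densities in mS/cm^2, potentials in mV. Tuned (scripted sweep; see the
# methods vignette) so that the cell rests near -64 mV without spontaneous
# firing and the reference black loom yields a firing profile peaking near
# projected collision. HCN is confined to field A; it is absent from
# field C.
densities:
  axon:  {na: 195, kdr: 150, hcn: 0,   kd: 0, km: 2, cat: 0,   kca: 0}
  SIZ:   {na: 150, kdr: 100, hcn: 0,   kd: 0, km: 2, cat: 0.5, kca: 4}
  trunk: {na: 0,   kdr: 0,   hcn: 0,   kd: 0, km: 0, cat: 0,   kca: 0}
  A:     {na: 0,   kdr: 0,   hcn: 0.5, kd: 3, km: 0, cat: 0,   kca: 0}
  B:     {na: 0,   kdr: 0,   hcn: 0,   kd: 0, km: 0, cat: 0,   kca: 0}
  C:     {na: 0,   kdr: 0,   hcn: 0,   kd: 0, km: 0, cat: 0,   kca: 0}
passive:
  axon:  {g_pas: 0.25, e_pas: -62}
  SIZ:   {g_pas: 0.25, e_pas: -62}
  trunk: {g_pas: 0.25, e_pas: -62}
  A:     {g_pas: 0.25, e_pas: -69}
  B:     {g_pas: 0.25, e_pas: -62}
  C:     {g_pas: 0.25, e_pas: -62}
reversals: {ena: 65, ek: -80, eh: -35, eca: 120}
# Spike-channel kinetics (sigmoid midpoints/slope, mV): Na activation and
# inactivation, delayed-rectifier activation.
kinetics: {na_m_vh: -48, na_m_k: 5.5, na_h_vh: -54, kdr_vh: -45}
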