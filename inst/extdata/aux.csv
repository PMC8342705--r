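sample_id,quantity,value,run
ZnO_S,zeta_mV,-10.9,1
ZnO_S,zeta_mV,-10.4,2
ZnO_S,zeta_mV,-11.4,3
ZnO_T,zeta_mV,-19.9,1
ZnO_T,zeta_mV,-21.2,2
ZnO_T,zeta_mV,-16.4,3
I,zeta_mV,-12.3,1
I,zeta_mV,-11.7,2
I,zeta_mV,-12.9,3
P,zeta_mV,5.98,1
P,zeta_mV,6.68,2
P,zeta_mV,5.62,3
IZnO_S,zeta_mV,-17.3,1
IZnO_S,zeta_mV,-18.3,2
IZnO_S,zeta_mV,-18.8,3
IZnO_T,zeta_mV,-16.2,1
IZnO_T,zeta_mV,-16.7,2
IZnO_T,zeta_mV,-17.4,3
PZnO_S,zeta_mV,15.2,1
PZnO_S,zeta_mV,15.2,2
PZnO_S,zeta_mV,15.3,3
PZnO_T,zeta_mV,6.38,1
PZnO_T,zeta_mV,6.84,2
PZnO_T,zeta_mV,6.84,3
IP,zeta_mV,13.5,1
IP,zeta_mV,12.9,2
IP,zeta_mV,13.4,3
IZnO_S_P,zeta_mV,13.3,1
IZnO_S_P,zeta_mV,13,2
IZnO_S_P,zeta_mV,12.4,3
IZnO_T_P,zeta_mV,9.96,1
IZnO_T_P,zeta_mV,11,2
IZnO_T_P,zeta_mV,11.7,3
I,enthalpy_J_per_g_degC,69.67,1
P,enthalpy_J_per_g_degC,103.28,1
ZnO_S,enthalpy_J_per_g_degC,8.08,1
ZnO_T,enthalpy_J_per_g_degC,7.13,1
IZnO_S,enthalpy_J_per_g_degC,62.15,1
IZnO_T,enthalpy_J_per_g_degC,38.26,1
PZnO_S,enthalpy_J_per_g_degC,107.7,1
PZnO_T,enthalpy_J_per_g_degC,125.35,1
IP,enthalpy_J_per_g_degC,213.35,1
IZnO_S_P,enthalpy_J_per_g_degC,83.67,1
IZnO_T_P,enthalpy_J_per_g_degC,120.44,1
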