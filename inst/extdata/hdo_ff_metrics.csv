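force_field,mode,metric,value,err
TIP3P,bend,omega0,1350.2,0.5
TIP3P,bend,sigma,26.0,0.3
TIP3P,bend,tau_c,0.23,0.02
TIP3P,OD,omega0,2520,2
TIP3P,OD,sigma,70,5
TIP3P,OD,tau_c,0.39,0.01
TIP3P,OH,omega0,3468,2
TIP3P,OH,sigma,95,7
TIP3P,OH,tau_c,0.43,0.03
SPC/E,bend,omega0,1339.8,0.5
SPC/E,bend,sigma,27.4,0.5
SPC/E,bend,tau_c,0.86,0.07
SPC/E,OD,omega0,2473,2
SPC/E,OD,sigma,82,6
SPC/E,OD,tau_c,0.80,0.04
SPC/E,OH,omega0,3406,2
SPC/E,OH,sigma,115,7
SPC/E,OH,tau_c,0.65,0.03
TIP4P/Ew,bend,omega0,1348.5,0.5
TIP4P/Ew,bend,sigma,25.5,0.6
TIP4P/Ew,bend,tau_c,0.40,0.03
TIP4P/Ew,OD,omega0,2498,2
TIP4P/Ew,OD,sigma,75,5
TIP4P/Ew,OD,tau_c,0.80,0.05
TIP4P/Ew,OH,omega0,3418,2
TIP4P/Ew,OH,sigma,109,6
TIP4P/Ew,OH,tau_c,0.83,0.05
OPC,bend,omega0,1341.2,0.5
OPC,bend,sigma,24,1
OPC,bend,tau_c,0.44,0.07
OPC,OD,omega0,2551,1
OPC,OD,sigma,63,2
OPC,OD,tau_c,0.64,0.02
OPC,OH,omega0,3507,2
OPC,OH,sigma,85,4
OPC,OH,tau_c,0.85,0.04
TIP5P,bend,omega0,1346.1,0.5
TIP5P,bend,sigma,25.8,0.6
TIP5P,bend,tau_c,0.95,0.05
TIP5P,OD,omega0,2488,2
TIP5P,OD,sigma,82,8
TIP5P,OD,tau_c,0.69,0.02
TIP5P,OH,omega0,3426,2
TIP5P,OH,sigma,110,10
TIP5P,OH,tau_c,1.09,0.03
MB-pol,bend,omega0,1340.9,0.6
MB-pol,bend,sigma,28.9,0.7
MB-pol,bend,tau_c,0.51,0.04
MB-pol,OD,omega0,2470,2
MB-pol,OD,sigma,82,5
MB-pol,OD,tau_c,1.21,0.06
MB-pol,OH,omega0,3403,2
MB-pol,OH,sigma,115,8
MB-pol,OH,tau_c,1.34,0.08
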