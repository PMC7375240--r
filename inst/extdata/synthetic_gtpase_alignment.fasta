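>RHOA_HUMAN/95-120 real fragment of P61586
IPEKWTPEVKHFCPNVPIILVGNKKD
>RHOB_SYNTHETIC Rho-family stand-in
IPDKWTPEVKHFCPNVPIILVANKKD
>RHOC_SYNTHETIC Rho-family stand-in
IPEKWTPEVKHFCPNVPIILVGNKKD
>KRAS_SYNTHETIC Ras stand-in
INNTKSFEDIHHYREQIKRVKDSEDV
>RAB7A_SYNTHETIC Rab stand-in
ILGNKI--DLESRAVSTERGQALAKE
>RAN_SYNTHETIC Ran stand-in
IWDTAGQEKFGGLRDGYYIQAQ--GA
>ARF1_SYNTHETIC Arf stand-in
IFANKQ--DLPNAMNAAEITDKLGLH
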