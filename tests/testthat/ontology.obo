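format-version: 1.2
ontology: synthetic

[Term]
id: GO:0000001
name: biological_process root
namespace: biological_process

[Term]
id: GO:0000002
name: biological_process L2 GO:0000001.1
namespace: biological_process
subset: goslim_synthetic
is_a: GO:0000001

[Term]
id: GO:0000003
name: biological_process L2 GO:0000001.2
namespace: biological_process
subset: goslim_synthetic
is_a: GO:0000001

[Term]
id: GO:0000004
name: biological_process L3 GO:0000002.1
namespace: biological_process
is_a: GO:0000002

[Term]
id: GO:0000005
name: biological_process L3 GO:0000002.2
namespace: biological_process
is_a: GO:0000002

[Term]
id: GO:0000006
name: biological_process L3 GO:0000003.1
namespace: biological_process
is_a: GO:0000003

[Term]
id: GO:0000007
name: biological_process L3 GO:0000003.2
namespace: biological_process
is_a: GO:0000003

[Term]
id: GO:0000008
name: biological_process L4 GO:0000004.1
namespace: biological_process
is_a: GO:0000004

[Term]
id: GO:0000009
name: biological_process L4 GO:0000004.2
namespace: biological_process
is_a: GO:0000004

[Term]
id: GO:0000010
name: biological_process L4 GO:0000005.1
namespace: biological_process
is_a: GO:0000005

[Term]
id: GO:0000011
name: biological_process L4 GO:0000005.2
namespace: biological_process
is_a: GO:0000005

[Term]
id: GO:0000012
name: biological_process L4 GO:0000006.1
namespace: biological_process
is_a: GO:0000006

[Term]
id: GO:0000013
name: biological_process L4 GO:0000006.2
namespace: biological_process
is_a: GO:0000006

[Term]
id: GO:0000014
name: biological_process L4 GO:0000007.1
namespace: biological_process
is_a: GO:0000007

[Term]
id: GO:0000015
name: biological_process L4 GO:0000007.2
namespace: biological_process
is_a: GO:0000007

[Term]
id: GO:0000016
name: molecular_function root
namespace: molecular_function

[Term]
id: GO:0000017
name: molecular_function L2 GO:0000016.1
namespace: molecular_function
subset: goslim_synthetic
is_a: GO:0000016

[Term]
id: GO:0000018
name: molecular_function L2 GO:0000016.2
namespace: molecular_function
subset: goslim_synthetic
is_a: GO:0000016

[Term]
id: GO:0000019
name: molecular_function L3 GO:0000017.1
namespace: molecular_function
is_a: GO:0000017

[Term]
id: GO:0000020
name: molecular_function L3 GO:0000017.2
namespace: molecular_function
is_a: GO:0000017

[Term]
id: GO:0000021
name: molecular_function L3 GO:0000018.1
namespace: molecular_function
is_a: GO:0000018

[Term]
id: GO:0000022
name: molecular_function L3 GO:0000018.2
namespace: molecular_function
is_a: GO:0000018

[Term]
id: GO:0000023
name: molecular_function L4 GO:0000019.1
namespace: molecular_function
is_a: GO:0000019

[Term]
id: GO:0000024
name: molecular_function L4 GO:0000019.2
namespace: molecular_function
is_a: GO:0000019

[Term]
id: GO:0000025
name: molecular_function L4 GO:0000020.1
namespace: molecular_function
is_a: GO:0000020

[Term]
id: GO:0000026
name: molecular_function L4 GO:0000020.2
namespace: molecular_function
is_a: GO:0000020

[Term]
id: GO:0000027
name: molecular_function L4 GO:0000021.1
namespace: molecular_function
is_a: GO:0000021

[Term]
id: GO:0000028
name: molecular_function L4 GO:0000021.2
namespace: molecular_function
is_a: GO:0000021

[Term]
id: GO:0000029
name: molecular_function L4 GO:0000022.1
namespace: molecular_function
is_a: GO:0000022

[Term]
id: GO:0000030
name: molecular_function L4 GO:0000022.2
namespace: molecular_function
is_a: GO:0000022

[Term]
id: GO:0000031
name: cellular_component root
namespace: cellular_component

[Term]
id: GO:0000032
name: cellular_component L2 GO:0000031.1
namespace: cellular_component
subset: goslim_synthetic
is_a: GO:0000031

[Term]
id: GO:0000033
name: cellular_component L2 GO:0000031.2
namespace: cellular_component
subset: goslim_synthetic
is_a: GO:0000031

[Term]
id: GO:0000034
name: cellular_component L3 GO:0000032.1
namespace: cellular_component
is_a: GO:0000032

[Term]
id: GO:0000035
name: cellular_component L3 GO:0000032.2
namespace: cellular_component
is_a: GO:0000032

[Term]
id: GO:0000036
name: cellular_component L3 GO:0000033.1
namespace: cellular_component
is_a: GO:0000033

[Term]
id: GO:0000037
name: cellular_component L3 GO:0000033.2
namespace: cellular_component
is_a: GO:0000033

[Term]
id: GO:0000038
name: cellular_component L4 GO:0000034.1
namespace: cellular_component
is_a: GO:0000034

[Term]
id: GO:0000039
name: cellular_component L4 GO:0000034.2
namespace: cellular_component
is_a: GO:0000034

[Term]
id: GO:0000040
name: cellular_component L4 GO:0000035.1
namespace: cellular_component
is_a: GO:0000035

[Term]
id: GO:0000041
name: cellular_component L4 GO:0000035.2
namespace: cellular_component
is_a: GO:0000035

[Term]
id: GO:0000042
name: cellular_component L4 GO:0000036.1
namespace: cellular_component
is_a: GO:0000036

[Term]
id: GO:0000043
name: cellular_component L4 GO:0000036.2
namespace: cellular_component
is_a: GO:0000036

[Term]
id: GO:0000044
name: cellular_component L4 GO:0000037.1
namespace: cellular_component
is_a: GO:0000037

[Term]
id: GO:0000045
name: cellular_component L4 GO:0000037.2
namespace: cellular_component
is_a: GO:0000037
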