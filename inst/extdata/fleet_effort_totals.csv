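super_fleet,fishery,effort,unit
trawl,South East Trawl Fishery 1985-2011,276933,operations
trawl,Great Australian Bight,82104,operations
trawl,Victorian Trawl Fishery state records (1978-1997),19984,operations
trawl,CSIRO trawl research,3135,operations
trawl,Victorian Inshore Trawl Fishery commonwealth records,956,operations
trawl,Victorian Trawl Fishery state records fish trawl,759,operations
trawl,Small Pelagic Fishery,754,operations
trawl,CSIRO trawl research in AFMA database,180,operations
trawl,AFZIS Foreign trawl 1974-1997,80,operations
trawl,High Seas South East Trawl,49,operations
trawl,Jack Mackerel Trawl,49,operations
trawl,AFMA AFZIS Radio Reporting database,49,operations
pelagic_longline,Victorian snapper fishery state records,12.0,million_hooks
pelagic_longline,Tuna Fishery,8.8,million_hooks
pelagic_longline,AFMA AFZIS Radio Reporting database,7.7,million_hooks
pelagic_longline,Southern and Western tuna and billfish fishery,0.6,million_hooks
pelagic_longline,Eastern Tuna and Billfish Fishery,0.07,million_hooks
demersal_longline,Gillnet Hook and Trap Fishery (auto-line),52.9,million_hooks
demersal_longline,Victorian shark fishery state records,9.7,million_hooks
demersal_longline,South East Non-Trawl Fishery (auto-line),5.2,million_hooks
demersal_longline,Gillnet Hook and Trap Fishery (bottom line),4.0,million_hooks
demersal_longline,Southern Shark Fishery (bottom line),1.1,million_hooks
demersal_longline,South East Non-Trawl Fishery (bottom line),0.7,million_hooks
demersal_longline,Southern Shark Hook Fishery (bottom line),0.12,million_hooks
demersal_longline,Southern Shark Gillnet Fishery (bottom line),0.01,million_hooks
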