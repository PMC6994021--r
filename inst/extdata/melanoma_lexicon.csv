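canonical,variant,adjuvant_flag
ipilimumab,ipilimumab,FALSE
ipilimumab,yervoy,FALSE
ipilimumab,ipi,FALSE
nivolumab,nivolumab,FALSE
nivolumab,opdivo,FALSE
nivolumab,nivo,FALSE
pembrolizumab,pembrolizumab,FALSE
pembrolizumab,keytruda,FALSE
pembrolizumab,pembro,FALSE
vemurafenib,vemurafenib,FALSE
vemurafenib,zelboraf,FALSE
dabrafenib,dabrafenib,FALSE
dabrafenib,tafinlar,FALSE
trametinib,trametinib,FALSE
trametinib,mekinist,FALSE
cobimetinib,cobimetinib,FALSE
cobimetinib,cotellic,FALSE
binimetinib,binimetinib,FALSE
binimetinib,mektovi,FALSE
encorafenib,encorafenib,FALSE
encorafenib,braftovi,FALSE
temozolomide,temozolomide,FALSE
temozolomide,temodar,FALSE
temozolomide,tmz,FALSE
dacarbazine,dacarbazine,FALSE
dacarbazine,dtic,FALSE
interferon,interferon,TRUE
interferon,intron,TRUE
interferon,ifn,TRUE
docetaxel,docetaxel,TRUE
docetaxel,taxotere,TRUE
paclitaxel,paclitaxel,FALSE
paclitaxel,taxol,FALSE
carboplatin,carboplatin,FALSE
carboplatin,paraplatin,FALSE
interleukin-2,interleukin-2,FALSE
interleukin-2,interleukin 2,FALSE
interleukin-2,proleukin,FALSE
interleukin-2,il-2,FALSE
interleukin-2,aldesleukin,FALSE
talimogene laherparepvec,talimogene laherparepvec,FALSE
talimogene laherparepvec,t-vec,FALSE
talimogene laherparepvec,tvec,FALSE
talimogene laherparepvec,imlygic,FALSE
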