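((((((sp002:0.488518212843,(sp009:0.376339902526,(sp013:0.32668565804,((sp025:0.118481867811,((sp029:0.0525972635347,sp033:0.0525972635347):0.0441971329639,sp036:0.0967943964986):0.0216874713128):0.166464587046,sp008:0.284946454858):0.0417392031823):0.0496542444862):0.112178310317):0.0751098073828,((sp024:0.0098856132671,sp010:0.0098856132671):0.175698697427,sp023:0.185584310694):0.378043709532):0.0218556321726,sp001:0.585483652399):0.051336547706,sp031:0.636820200105):0.158271530047,sp015:0.795091730151):0.204908269849,(((((((sp032:0.159663136873,sp018:0.159663136873):0.124420933078,((sp034:0.105411993898,sp003:0.105411993898):0.165948047301,(((sp012:0.00441454472819,sp026:0.00441454472819):0.154007176769,sp027:0.158421721497):0.068841227817,sp016:0.227262949314):0.0440970918843):0.0127240287533):0.0135523442267,sp011:0.297636414178):0.11693092568,(sp017:0.392536031328,sp007:0.392536031328):0.0220313085297):0.112788612695,((sp030:0.0649094914112,sp035:0.0649094914112):0.285901591458,sp028:0.35081108287):0.176544869683):0.0790994190816,((sp006:0.0904672133518,(sp014:0.0112827566563,sp004:0.0112827566563):0.0791844566955):0.454736838579,((sp022:0.141253633924,sp005:0.141253633924):0.0610679698427,sp021:0.202321603767):0.342882448164):0.0612513197036):0.213241726082,(sp020:0.351648686165,sp019:0.351648686165):0.468048411551):0.180302902284);
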